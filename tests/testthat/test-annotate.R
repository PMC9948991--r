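# tRNA-window filtering, TSS distances, site collapsing, KDE profiles,
# occupancy aggregation, summary tables.

test_that("near-feature filter applies strand-aware flanks with inclusive bounds", {
    trna <- GRanges("chrI", IRanges(5001, 5072), strand = "+")  # BED [5000,5072)
    keepNear <- makePreds("chrI", 4500L, 4505L, "TY1")
    expect_length(nearFeatureFilter(keepNear, trna), 1)

    dropFar <- makePreds("chrI", 5600L, 5605L, "TY1")   # > 500 past the end
    expect_length(nearFeatureFilter(dropFar, trna), 0)
    edge <- makePreds("chrI", 5571L, 5572L, "TY1")      # last downstream base
    expect_length(nearFeatureFilter(edge, trna), 1)

    # minus strand: upstream flank extends rightward
    trnaM <- GRanges("chrI", IRanges(5001, 5072), strand = "-")
    right <- makePreds("chrI", 5600L, 5605L, "TY1")
    expect_length(nearFeatureFilter(right, trnaM), 1)
    left <- makePreds("chrI", 4200L, 4205L, "TY1")      # > 500 upstream-left
    expect_length(nearFeatureFilter(left, trnaM), 0)

    expect_error(nearFeatureFilter(keepNear, trna, upstream = -1), ">= 0")
})

test_that("near-feature filter agrees with a brute-force all-pairs check", {
    set.seed(41)
    for (rep_ in 1:10) {
        nP <- 300; nF <- 40
        preds <- makePreds(sample(c("chrI", "chrII"), nP, TRUE),
                           s0 <- sample(0:99000, nP), s0 + 5L, "TY1")
        fs <- sample(0:95000, nF)
        feats <- GRanges(sample(c("chrI", "chrII"), nF, TRUE),
                         IRanges(fs + 1, fs + 72),
                         strand = sample(c("+", "-"), nF, TRUE))
        got <- nearFeatureFilter(preds, feats, 1000, 500)
        inWin <- vapply(seq_len(nP), function(i) {
            any(vapply(seq_len(nF), function(j) {
                if (as.character(seqnames(preds))[i] !=
                    as.character(seqnames(feats))[j]) return(FALSE)
                up <- 1000; dn <- 500
                if (as.character(strand(feats))[j] == "+") {
                    ws <- start(feats)[j] - up; we <- end(feats)[j] + dn
                } else {
                    ws <- start(feats)[j] - dn; we <- end(feats)[j] + up
                }
                start(preds)[i] <= we && end(preds)[i] >= ws
            }, TRUE))
        }, TRUE)
        expect_identical(start(got), start(preds)[inWin])
    }
})

test_that("signed TSS distance is feature-relative with upstream negative", {
    plus <- GRanges("chrI", IRanges(1001, 1072), strand = "+")  # TSS at 1001
    p <- makePreds("chrI", 983L, 988L, "TY3")                   # midpoint 986
    expect_equal(nearestTssDistance(p, plus), -15)

    minus <- GRanges("chrI", IRanges(1001, 1072), strand = "-") # TSS at 1072
    pm <- makePreds("chrI", 1084L, 1089L, "TY3")                # midpoint 1087
    expect_equal(nearestTssDistance(pm, minus), -15)

    atTss <- makePreds("chrI", 998L, 1003L, "TY3")              # midpoint 1001
    expect_equal(nearestTssDistance(atTss, plus), 0)

    # nearest feature wins; NA with warning off-chromosome
    two <- c(plus, GRanges("chrI", IRanges(2001, 2072), strand = "+"))
    near2 <- makePreds("chrI", 1995L, 2000L, "TY3")             # midpoint 1998
    expect_equal(nearestTssDistance(near2, two), -3)
    off <- makePreds("chrZ", 10L, 15L, "TY3")
    expect_warning(d <- nearestTssDistance(off, two), "without features")
    expect_true(is.na(d))
})

test_that("signed distances are invariant under coordinate reflection", {
    set.seed(42)
    L <- 10000L
    n <- 50
    s0 <- sample(500:9000, n)
    preds <- makePreds("chrI", s0, s0 + 5L, "TY1")
    fs <- sample(500:9000, 8)
    feats <- GRanges("chrI", IRanges(fs + 1, fs + 72),
                     strand = sample(c("+", "-"), 8, TRUE))
    d1 <- nearestTssDistance(preds, feats)
    # reflect everything through position L: strand flips, intervals mirror
    refl <- function(gr) {
        out <- GRanges(seqnames(gr),
            IRanges(start = L - end(gr) + 1, end = L - start(gr) + 1),
            strand = ifelse(as.character(strand(gr)) == "+", "-", "+"))
        mcols(out) <- mcols(gr)
        out
    }
    d2 <- nearestTssDistance(refl(preds), refl(feats))
    expect_equal(d2, d1)
})

test_that("non-redundant collapsing keys on site, strand and family", {
    same <- do.call(c, replicate(900, makePreds("chrI", 100L, 105L, "TY1"),
                                 simplify = FALSE))
    nr <- nonredundantSites(same)
    expect_length(nr, 1)
    expect_identical(mcols(nr)$count, 900L)

    twoFam <- c(makePreds("chrI", 100L, 105L, "TY1"),
                makePreds("chrI", 100L, 105L, "TY2"))
    expect_length(nonredundantSites(twoFam), 2)

    expect_length(nonredundantSites(twoFam[0]), 0)
})

test_that("KDE profile matches the prescribed bandwidth and normalizes", {
    set.seed(43)
    x <- rnorm(500, sd = 100)
    prof <- kdeProfile(x)
    expect_equal(attr(prof, "bandwidth"), 0.4 * stats::bw.nrd0(x))
    integral <- sum(diff(prof$position) *
        (head(prof$density, -1) + tail(prof$density, -1)) / 2)
    expect_lt(abs(integral - 1), 1e-3)

    # two points: symmetric about 0
    sym <- kdeProfile(c(-50, 50), from = -200, to = 200, n = 401)
    expect_lt(max(abs(sym$density - rev(sym$density))), 1e-9)

    expect_error(kdeProfile(5), "at least two")
    expect_error(kdeProfile(c(3, 3, 3)), "zero spread")
})

test_that("KDE of a large normal sample approaches the analytic density", {
    set.seed(44)
    sups <- vapply(1:5, function(i) {
        x <- rnorm(10000)
        prof <- kdeProfile(x, bandwidthFactor = 1)
        max(abs(prof$density - dnorm(prof$position)))
    }, 0)
    expect_lt(median(sups), 0.02)
})

test_that("signal aggregation orients windows 5'->3' and averages", {
    # constant track: flat curve
    tr <- S4Vectors::SimpleList(chrI = S4Vectors::Rle(rep(2.5, 6000)))
    feats <- GRanges("chrI", IRanges(c(3001, 4001), width = 72),
                     strand = c("+", "-"))
    prof <- aggregateSignal(tr, feats, upstream = 2000, downstream = 500)
    expect_identical(nrow(prof), 2500L)
    expect_identical(prof$position[1], -2000L)
    expect_true(all(prof$value == 2.5))

    # single plus-strand feature: the raw track slice
    set.seed(45)
    vals <- runif(6000)
    tr2 <- S4Vectors::SimpleList(chrI = S4Vectors::Rle(vals))
    f1 <- GRanges("chrI", IRanges(3001, 3072), strand = "+")
    p1 <- aggregateSignal(tr2, f1, 2000, 500)
    expect_equal(p1$value, vals[1001:3500])

    # mirror-image track: + and - features contribute identically
    f2 <- GRanges("chrI", IRanges(3001, 3072), strand = "-")
    mirror <- numeric(6000)
    tssPlus <- 3001; tssMinus <- 3072
    rel <- -2000:499
    mirror[tssMinus - rel] <- vals[tssPlus + rel]
    tr3 <- S4Vectors::SimpleList(chrI = S4Vectors::Rle(mirror))
    p2 <- aggregateSignal(tr3, f2, 2000, 500)
    expect_equal(p2$value, p1$value)

    expect_error(aggregateSignal(
        S4Vectors::SimpleList(chrZ = S4Vectors::Rle(1, 10)), f1),
        "no feature")
})

test_that("family tables report counts, medians, tRNA partition and correlations", {
    feats <- GRanges("chrI", IRanges(5001, 5072), strand = "+")
    mk <- function(method, sample, n, near = TRUE) {
        s0 <- if (near) 4500L + seq_len(n) else 20000L + seq_len(n) * 10L
        makePreds(rep("chrI", n), s0, s0 + 5L, "TY1", method = method,
                  sample = sample)
    }
    preds <- c(mk("m1", "s1", 40), mk("m1", "s2", 50), mk("m1", "s3", 60),
               mk("m2", "s1", 40), mk("m2", "s2", 50), mk("m2", "s3", 60))
    tabs <- familyTables(preds, feats)
    expect_equal(tabs$medians$median_n[tabs$medians$method == "m1"], 50)
    expect_equal(unname(tabs$correlation["m1", "m2"]), 1)

    # 8 of 10 predictions near tRNA -> 80%
    part <- c(mk("m3", "s1", 8, near = TRUE), mk("m3", "s1", 2, near = FALSE))
    tab3 <- familyTables(part, feats)
    row <- tab3$perFamily[tab3$perFamily$method == "m3", ]
    expect_equal(row$pct_near_trna, 80)

    expect_error(familyTables(mk("m1", "s1", 3), feats[0],
                              cor_method = "pearson"), NA)
})
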