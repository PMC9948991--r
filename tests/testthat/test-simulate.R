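# Insertion planning, synthetic genome construction, read simulation,
# down-sampling.

test_that("a forced plan is unique and planning is deterministic", {
    g <- tinyGenome()
    lib <- teLibrary(c(TY1 = "TTTT"))
    site <- GRanges("chrI", IRanges(3, 3))    # 1-bp site
    p1 <- planInsertion(g, lib, site, strandPolicy = "fixed+", seed = 11)
    p2 <- planInsertion(g, lib, site, strandPolicy = "fixed+", seed = 99)
    expect_identical(p1@breakpoint, 2L)       # 0-based
    expect_identical(p1@family, "TY1")
    expect_identical(p1@strand, "+")
    expect_identical(p1@breakpoint, p2@breakpoint)

    p3 <- planInsertion(g, lib, site, seed = 5)
    p4 <- planInsertion(g, lib, site, seed = 5)
    expect_identical(p3@strand, p4@strand)
    expect_identical(p3@family, p4@family)

    expect_error(planInsertion(g, lib, site[0]), "empty")
})

test_that("equal-width sites are chosen uniformly", {
    set.seed(404)
    g <- randomGenome(c(chrI = 2000L))
    lib <- teLibrary(c(TY1 = "TTTT"))
    sites <- GRanges("chrI", IRanges(c(101, 1001), width = 100))
    picks <- withr::with_seed(2024, vapply(seq_len(10000), function(i)
        planInsertion(g, lib, sites, tsdLen = 0L)@breakpoint < 500, TRUE))
    # oracle: two-sided multinomial balance check at alpha = 0.01
    expect_gt(chisq.test(table(picks), p = c(0.5, 0.5))$p.value, 0.01)
})

test_that("synthetic genome construction duplicates the target site", {
    g <- DNAStringSet(c(chrI = "ACGTACGTAC"))
    lib <- teLibrary(c(TY1 = "TTTT"))
    syn <- buildSyntheticGenome(g, lib,
        tebench:::insertionPlan("chrI", 4L, "TY1", "+", 2L))
    expect_identical(as.character(syn$genome[["chrI"]]), "ACGTACTTTTACGTAC")
    expect_identical(length(syn$genome[["chrI"]]), 16L)
    expect_identical(start(syn$truth), 5L)    # TSD [4,6) 0-based
    expect_identical(end(syn$truth), 6L)

    # zero-length TSD: pure insertion
    syn0 <- buildSyntheticGenome(g, lib,
        tebench:::insertionPlan("chrI", 4L, "TY1", "+", 0L))
    expect_identical(length(syn0$genome[["chrI"]]), 14L)
    expect_identical(as.character(syn0$genome[["chrI"]]), "ACGTTTTTACGTAC")

    expect_error(buildSyntheticGenome(g, lib,
        tebench:::insertionPlan("chrI", 9L, "TY1", "+", 2L)), "exceeds")
    expect_error(buildSyntheticGenome(g, lib,
        tebench:::insertionPlan("chrI", 4L, "TY9", "+", 2L)), "TY9")
})

test_that("5-bp TSDs leave identical flanks around the inserted element", {
    set.seed(31)
    g <- randomGenome(c(chrI = 500L))
    lib <- teLibrary(c(TY1 = paste(sample(c("A", "C", "G", "T"), 60,
                                          replace = TRUE), collapse = "")))
    p0 <- 200L
    syn <- buildSyntheticGenome(g, lib,
        tebench:::insertionPlan("chrI", p0, "TY1", "+", 5L))
    s <- syn$genome[["chrI"]]
    left <- subseq(s, p0 + 1L, p0 + 5L)              # TSD copy before TE
    right <- subseq(s, p0 + 5L + 60L + 1L, p0 + 5L + 60L + 5L)
    expect_identical(as.character(left), as.character(right))
    expect_identical(as.character(left),
        as.character(subseq(g[["chrI"]], p0 + 1L, p0 + 5L)))
})

test_that("length conservation and reference reconstruction hold over random plans", {
    set.seed(77)
    lib <- tinyLibrary()
    for (i in 1:25) {
        g <- randomGenome(c(chrA = sample(50:200, 1)))
        L <- width(g)[1]
        tsd <- sample(0:6, 1)
        p0 <- sample(0:(L - tsd), 1)
        fam <- sample(names(teConsensus(lib)), 1)
        strand <- sample(c("+", "-"), 1)
        syn <- buildSyntheticGenome(g, lib,
            tebench:::insertionPlan("chrA", p0, fam, strand, tsd))
        te <- teConsensus(lib)[[fam]]
        expect_identical(length(syn$genome[["chrA"]]) - L,
                         length(te) + tsd)
        # removing TE plus one TSD copy reconstructs the reference
        s <- as.character(syn$genome[["chrA"]])
        rebuilt <- paste0(substr(s, 1, p0 + tsd),
                          substr(s, p0 + 2 * tsd + length(te) + 1,
                                 nchar(s)))
        expect_identical(rebuilt, as.character(g[["chrA"]]))
        # minus-strand insert is the reverse complement of the plus insert
        ins <- substr(s, p0 + tsd + 1, p0 + tsd + length(te))
        expected <- if (strand == "-")
            as.character(reverseComplement(te)) else as.character(te)
        expect_identical(ins, expected)
    }
})

test_that("read counts follow the coverage formula and reads match the genome", {
    set.seed(5)
    g <- randomGenome(c(chrI = 10000L))
    rs <- simulateReads(g, coverage = 10, readLen = 100L, insertMean = 300,
                        insertSd = 30, errorRate = 0, seed = 21)
    expect_identical(nFragments(rs), 500L)   # round(10 * 10000 / 200)
    expect_identical(unique(width(mate1(rs))), 100L)
    expect_identical(names(mate1(rs)), names(mate2(rs)))

    # with no errors every mate is an exact (revcomp-aware) substring
    gs <- as.character(g[[1]])
    idx <- sample(nFragments(rs), 25)
    for (i in idx) {
        expect_true(grepl(as.character(mate1(rs)[[i]]), gs, fixed = TRUE))
        expect_true(grepl(as.character(
            reverseComplement(mate2(rs)[[i]])), gs, fixed = TRUE))
    }
})

test_that("single-end mode emits forward reads only at half the pair count", {
    set.seed(6)
    g <- randomGenome(c(chrI = 5000L))
    rs <- simulateReads(g, coverage = 4, readLen = 50L, paired = FALSE,
                        errorRate = 0, seed = 3)
    expect_identical(nFragments(rs), 400L)   # round(4 * 5000 / 50)
    expect_length(mate2(rs), 0)
})

test_that("error injection perturbs roughly errorRate of bases", {
    set.seed(8)
    g <- randomGenome(c(chrI = 20000L))
    rs0 <- simulateReads(g, 10, readLen = 100L, errorRate = 0, seed = 77)
    rs1 <- simulateReads(g, 10, readLen = 100L, errorRate = 0.01, seed = 77)
    # same seed, same layout: differences are exactly the injected errors
    m0 <- paste(as.character(mate1(rs0)), collapse = "")
    m1 <- paste(as.character(mate1(rs1)), collapse = "")
    nDiff <- sum(strsplit(m0, "")[[1]] != strsplit(m1, "")[[1]])
    nBases <- nchar(m0)
    expect_lt(abs(nDiff / nBases - 0.01), 3 * sqrt(0.01 * 0.99 / nBases))
})

test_that("empirical depth matches the target coverage", {
    set.seed(9)
    lens <- c(chrI = 100000L)
    g <- randomGenome(lens)
    rs <- simulateReads(g, coverage = 50, readLen = 100L, insertMean = 300,
                        insertSd = 30, errorRate = 0, seed = 13)
    depth <- readDepthTrack(rs, lens)
    meanDepth <- mean(as.numeric(depth$chrI))
    expect_lt(abs(meanDepth - 50), 3 * sqrt(50 / lens[[1]]) * 50)
    # interior positions (away from edge effects) also sit near target
    mid <- as.numeric(depth$chrI[400:99600])
    expect_lt(abs(mean(mid) - 50), 3 * sqrt(50))
})

test_that("read simulation is byte-deterministic given the seed", {
    set.seed(10)
    g <- randomGenome(c(chrI = 3000L))
    p1 <- withr::local_tempdir()
    rs1 <- simulateReads(g, 5, readLen = 60L, errorRate = 0.01, seed = 12)
    rs2 <- simulateReads(g, 5, readLen = 60L, errorRate = 0.01, seed = 12)
    f1 <- writeReadSet(rs1, file.path(p1, "a"))
    f2 <- writeReadSet(rs2, file.path(p1, "b"))
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("downsampling keeps mates together at the binomial rate", {
    set.seed(11)
    g <- randomGenome(c(chrI = 101000L))
    rs <- simulateReads(g, coverage = 20, readLen = 101L, errorRate = 0,
                        seed = 14)
    n <- nFragments(rs)
    expect_identical(downsampleReads(rs, 50, 50), rs)   # identity
    down <- downsampleReads(rs, 100, 50, seed = 15)
    kept <- nFragments(down)
    expect_lt(abs(kept - 0.5 * n), 3 * sqrt(n * 0.25))
    expect_identical(names(mate1(down)), names(mate2(down)))
    expect_true(all(names(mate1(down)) %in% names(mate1(rs))))
    down2 <- downsampleReads(rs, 100, 50, seed = 15)
    expect_identical(as.character(mate1(down2)), as.character(mate1(down)))
    expect_error(downsampleReads(rs, 100, 0), "target")
})
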