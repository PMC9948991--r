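# Shared in-code fixtures for the test suite.

suppressPackageStartupMessages({
    library(Biostrings)
    library(GenomicRanges)
    library(IRanges)
})

tinyGenome <- function() {
    DNAStringSet(c(chrI = "ACGTACGTAC", chrII = "GGGGTTTTCCCCAAAA"))
}

tinyLibrary <- function() {
    teLibrary(c(TY1 = "TTTT", TY2 = "ACACAC"))
}

# Random genome of given chromosome lengths (seeded by the caller).
randomGenome <- function(lens) {
    x <- DNAStringSet(vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), ""))
    names(x) <- names(lens)
    x
}

# Build a prediction GRanges from parallel vectors (BED 0-based inputs).
makePreds <- function(chrom, start0, end0, family, strand = "+",
                      category = "non-reference", method = "stub",
                      sample = "s1") {
    GRanges(chrom, IRanges(start = start0 + 1, end = end0),
            strand = rep(strand, length.out = length(chrom)),
            family = rep(family, length.out = length(chrom)),
            category = rep(category, length.out = length(chrom)),
            method = rep(method, length.out = length(chrom)),
            sample = rep(sample, length.out = length(chrom)))
}

makeTruth <- function(chrom, tsdStart0, tsdLen, family, strand = "+") {
    GRanges(chrom, IRanges(start = tsdStart0 + 1, width = tsdLen),
            strand = strand, family = family, tsdLen = tsdLen)
}

# Independent brute-force within-N classifier used as the oracle for the
# evaluator: enumerates every (prediction, N) pair with scalar arithmetic,
# no shared code with tallyReplicate().
bruteForceTally <- function(truth, predictions, windows) {
    ts <- start(truth); te <- end(truth)
    tchr <- as.character(seqnames(truth))
    tfam <- mcols(truth)$family
    tstr <- as.character(strand(truth))
    isNonref <- mcols(predictions)$category == "non-reference"
    rows <- lapply(windows, function(N) {
        hit <- FALSE
        nWithin <- 0L
        for (i in which(isNonref)) {
            p <- predictions[i]
            ok <- as.character(seqnames(p)) == tchr &&
                mcols(p)$family == tfam &&
                as.character(strand(p)) == tstr &&
                abs(start(p) - ts) <= N && abs(end(p) - te) <= N
            if (ok) { hit <- TRUE; nWithin <- nWithin + 1L }
        }
        tp <- as.integer(hit)
        data.frame(window = N, TP = tp, FP = sum(isNonref) - tp,
                   FN = 1L - tp, n_within = nWithin,
                   n_nonref = sum(isNonref),
                   n_ref = sum(!isNonref))
    })
    do.call(rbind, rows)
}

# Random single-replicate scoring fixture: one truth plus a mixed bag of
# predictions (near-hits, wrong family/strand, other chromosomes).
randomScoringFixture <- function(maxPreds = 20L) {
    fams <- c("TY1", "TY2", "TY3")
    chroms <- c("chrI", "chrII")
    truth <- makeTruth(sample(chroms, 1), sample(0:5000, 1), 5L,
                       sample(fams, 1), sample(c("+", "-"), 1))
    n <- sample.int(maxPreds, 1L) - 1L
    if (n == 0L)
        return(list(truth = truth,
                    preds = makePreds(character(), integer(), integer(),
                                      character())))
    offs <- sample(c(-600:600), n, replace = TRUE)
    w <- sample(0:10, n, replace = TRUE)
    s0 <- pmax(start(truth) - 1 + offs, 0)
    preds <- makePreds(sample(chroms, n, replace = TRUE), s0, s0 + w,
                       sample(fams, n, replace = TRUE),
                       strand = sample(c("+", "-", "*"), n, replace = TRUE),
                       category = sample(c("non-reference", "reference"),
                                         n, replace = TRUE, prob = c(.8, .2)))
    # some predictions land on the truth exactly
    nExact <- rbinom(1, 1, 0.5)
    if (nExact > 0) {
        exact <- truth
        mcols(exact) <- S4Vectors::DataFrame(
            family = mcols(truth)$family, category = "non-reference",
            method = "stub", sample = "s1")
        preds <- suppressWarnings(c(preds, exact))  # seqlevel merge notes
    }
    list(truth = truth, preds = preds)
}
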