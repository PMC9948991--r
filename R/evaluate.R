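# Scoring of detector predictions against the synthetic truth with the
# within-N classification, and summarization of replicates into
# recall/precision curves.

#' Classify predictions as within-N of the truth
#'
#' A prediction is within-N when it is on the truth's chromosome, matches
#' the truth's family and strand, and both of its endpoints fall within N
#' bp of the corresponding endpoints of the truth TSD interval
#' (`|start - tsd_start| <= N` and `|end - tsd_end| <= N`). At N = 0 this
#' reduces to identical start and end coordinates. A prediction with
#' unknown strand (`"*"`/`"."`) is a mismatch unless `ignoreStrand =
#' TRUE`.
#'
#' @param truth One-record truth `GRanges` (from
#'   [buildSyntheticGenome()]).
#' @param predictions Prediction `GRanges` with a `family` metadata
#'   column.
#' @param N Window size in bp (>= 0).
#' @param ignoreStrand Accept predictions regardless of strand.
#' @return Logical vector along `predictions`.
#' @export
classifyWithinN <- function(truth, predictions, N, ignoreStrand = FALSE) {
    stopifnot(length(truth) == 1L, N >= 0)
    if (!length(predictions)) return(logical())
    sameChrom <- as.character(GenomicRanges::seqnames(predictions)) ==
        as.character(GenomicRanges::seqnames(truth))
    sameFam <- GenomicRanges::mcols(predictions)$family ==
        GenomicRanges::mcols(truth)$family
    sameStrand <- if (ignoreStrand) rep(TRUE, length(predictions))
        else as.character(GenomicRanges::strand(predictions)) ==
            as.character(GenomicRanges::strand(truth))
    dStart <- abs(GenomicRanges::start(predictions) -
                  GenomicRanges::start(truth))
    dEnd <- abs(GenomicRanges::end(predictions) - GenomicRanges::end(truth))
    sameChrom & sameFam & sameStrand & dStart <= N & dEnd <= N
}

#' Tally one replicate against the truth
#'
#' Implements the single-insertion scoring rules: per window N, TP = 1 if
#' at least one non-reference prediction classifies within-N (only one
#' prediction can be a true positive; all other non-reference predictions
#' are false positives), FN = 1 - TP, and FP = (total non-reference
#' predictions) - TP. When several predictions classify, the one whose
#' start is nearest the truth start is recorded as the match (counts are
#' unaffected). Reference-category predictions never enter TP/FP/FN; they
#' are only counted for the mean-count summaries.
#'
#' @param truth One-record truth `GRanges`.
#' @param predictions Prediction `GRanges` (metadata `family`,
#'   `category`).
#' @param windows Integer vector of window sizes, non-empty.
#' @param ignoreStrand Passed to [classifyWithinN()].
#' @return A `data.frame` with one row per window: `window`, `TP`, `FP`,
#'   `FN`, `n_within`, `n_nonref`, `n_ref`; the matched prediction index
#'   per window is attached as attribute `"matched"`.
#' @export
tallyReplicate <- function(truth, predictions, windows,
                           ignoreStrand = FALSE) {
    if (!length(windows)) stopf("windows must be non-empty")
    cat_ <- GenomicRanges::mcols(predictions)$category
    if (is.null(cat_)) cat_ <- rep("non-reference", length(predictions))
    nonrefIdx <- which(cat_ == "non-reference")
    nonref <- predictions[nonrefIdx]
    nNonref <- length(nonref)
    nRef <- length(predictions) - nNonref
    matched <- integer(length(windows))
    rows <- lapply(seq_along(windows), function(i) {
        ok <- classifyWithinN(truth, nonref, windows[i], ignoreStrand)
        tp <- as.integer(any(ok))
        if (tp == 1L) {
            hits <- which(ok)
            d <- abs(GenomicRanges::start(nonref)[hits] -
                     GenomicRanges::start(truth))
            matched[i] <<- nonrefIdx[hits[which.min(d)]]
        }
        data.frame(window = windows[i], TP = tp, FP = nNonref - tp,
                   FN = 1L - tp, n_within = sum(ok), n_nonref = nNonref,
                   n_ref = nRef)
    })
    out <- do.call(rbind, rows)
    attr(out, "matched") <- matched
    out
}

#' Summarize replicate tallies into metrics rows
#'
#' Sums TP/FP/FN across replicates per window, then computes recall =
#' TP/(TP+FN) and precision = TP/(TP+FP). Precision is reported as `NA`
#' (missing, never 0) when TP+FP = 0. Mean non-reference and reference
#' prediction counts per replicate are reported overall
#' (`mean_nonref`/`mean_ref`) and within each window (`mean_within`).
#'
#' @param tallies List of tallies from [tallyReplicate()] (same windows).
#' @return A `data.frame` with one row per window: `window`, `TP`, `FP`,
#'   `FN`, `recall`, `precision`, `mean_within`, `mean_nonref`,
#'   `mean_ref`.
#' @export
metricsFromTallies <- function(tallies) {
    if (!length(tallies)) stopf("at least one replicate tally is required")
    windows <- tallies[[1L]]$window
    for (t in tallies)
        if (!identical(t$window, windows))
            stopf("tallies have mismatched windows")
    all <- do.call(rbind, tallies)
    agg <- lapply(split(all, factor(all$window, levels = windows)),
                  function(d) {
        tp <- sum(d$TP); fp <- sum(d$FP); fn <- sum(d$FN)
        data.frame(window = d$window[1L], TP = tp, FP = fp, FN = fn,
            recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
            precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
            mean_within = mean(d$n_within), mean_nonref = mean(d$n_nonref),
            mean_ref = mean(d$n_ref))
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
}

#' Build a precision/recall table across fold-coverages
#'
#' @param resultsByCoverage Named list (names = coverages) of lists of
#'   replicate tallies, as accumulated by [runBenchmark()].
#' @return A long-format `data.frame`, one row per (coverage, window),
#'   with the columns of [metricsFromTallies()] plus `coverage`; ready
#'   for CSV output.
#' @export
precisionRecallCurve <- function(resultsByCoverage) {
    if (!length(resultsByCoverage)) stopf("at least one coverage is required")
    if (is.null(names(resultsByCoverage)))
        stopf("resultsByCoverage must be named by coverage")
    rows <- lapply(names(resultsByCoverage), function(cov) {
        m <- metricsFromTallies(resultsByCoverage[[cov]])
        cbind(coverage = as.numeric(cov), m)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a metrics table as CSV
#'
#' Undefined (missing) precision is written as an empty cell, never 0.
#'
#' @param metrics `data.frame` from [metricsFromTallies()] or
#'   [precisionRecallCurve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMetricsCsv <- function(metrics, path) {
    write.csv(metrics, path, row.names = FALSE, na = "")
    invisible(path)
}
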