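# Depth-of-coverage TE copy-number estimation: mean depth over a TE
# consensus (or its internal coding region) normalized by mean depth in
# non-repetitive regions of the genome, plus a Poisson depth generator so
# the estimator is testable without alignment.

#' Background depth over non-repetitive regions
#'
#' Mean per-base depth over the union of the given intervals (overlaps
#' deduplicated so each base counts once). Positions the track does not
#' cover are ignored with a warning.
#'
#' @param track Depth track (list of numeric `Rle` per chromosome, as from
#'   [readTrack()]).
#' @param nonrepetitive `GRanges` of non-repetitive regions; non-empty.
#' @return Scalar mean depth.
#' @export
backgroundDepth <- function(track, nonrepetitive) {
    if (!length(nonrepetitive))
        stopf("non-repetitive interval set is empty")
    red <- GenomicRanges::reduce(nonrepetitive, ignore.strand = TRUE)
    vals <- numeric()
    nMissing <- 0L
    for (i in seq_along(red)) {
        ch <- as.character(GenomicRanges::seqnames(red))[i]
        s <- GenomicRanges::start(red)[i]
        e <- GenomicRanges::end(red)[i]
        if (!ch %in% names(track)) {
            nMissing <- nMissing + (e - s + 1L)
            next
        }
        r <- track[[ch]]
        eClip <- min(e, length(r))
        if (eClip < e) nMissing <- nMissing + (e - eClip)
        if (s > eClip) next
        v <- as.numeric(r[s:eClip])
        nMissing <- nMissing + sum(is.na(v))
        vals <- c(vals, v[!is.na(v)])
    }
    if (nMissing > 0L)
        warnf("%d position(s) not covered by the track were ignored",
              nMissing)
    if (!length(vals))
        stopf("no covered positions in the non-repetitive intervals")
    mean(vals)
}

#' Depth-normalized TE copy number
#'
#' Mean (or median) depth over a region of the TE consensus divided by the
#' background depth. The region defaults to the whole consensus minus
#' `edgeTrim` bp at each end; restricting it to the internal coding region
#' estimates full-length copy number (solo LTRs contribute no internal
#' sequence).
#'
#' @param teTrack Numeric `Rle` (or vector) of per-base depth along the
#'   consensus.
#' @param background Background depth (> 0), from [backgroundDepth()].
#' @param region Optional length-2 numeric, 0-based half-open sub-interval
#'   of the consensus (e.g. the internal coding region).
#' @param edgeTrim Bases trimmed from each consensus end when `region` is
#'   not given (consensus termini are systematically under-covered in real
#'   alignments).
#' @param stat `"mean"` (default) or `"median"`.
#' @return Scalar copy-number estimate.
#' @examples
#' teCopyNumber(rep(30, 100), background = 10)  # 3
#' @export
teCopyNumber <- function(teTrack, background, region = NULL, edgeTrim = 0L,
                         stat = c("mean", "median")) {
    stat <- match.arg(stat)
    if (background <= 0) stopf("background depth must be > 0")
    v <- as.numeric(teTrack)
    len <- length(v)
    if (is.null(region)) {
        lo <- 1L + as.integer(edgeTrim)
        hi <- len - as.integer(edgeTrim)
    } else {
        if (length(region) != 2L || region[1L] < 0 || region[2L] > len)
            stopf("region must be a 0-based half-open interval within the consensus")
        lo <- as.integer(region[1L]) + 1L
        hi <- as.integer(region[2L])
    }
    if (hi < lo)
        stopf("region shorter than 1 bp after trimming")
    vv <- v[lo:hi]
    vv <- vv[!is.na(vv)]
    if (!length(vv)) stopf("no covered positions in the region")
    est <- if (stat == "mean") mean(vv) else median(vv)
    est / background
}

#' Simulate a Poisson depth track
#'
#' Per-position depths drawn i.i.d. Poisson(`copyNumber * background`);
#' the fixture generator for testing the copy-number estimator.
#'
#' @param copyNumber True copy number (>= 0).
#' @param background Background depth (> 0).
#' @param length Track length in bp (>= 1).
#' @param seed Integer seed, or `NULL`.
#' @return Numeric `Rle` of per-base depth.
#' @export
simulateDepth <- function(copyNumber, background, length, seed = NULL) {
    if (copyNumber < 0) stopf("copy number must be >= 0")
    if (background <= 0) stopf("background depth must be > 0")
    if (length < 1) stopf("length must be >= 1")
    withSeed(seed,
        S4Vectors::Rle(as.numeric(rpois(length, copyNumber * background))))
}
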