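# The end-to-end "simulate -> detect -> evaluate" driver with pluggable
# detector stubs, replacing cluster orchestration with sequential
# desk-scale execution.

#' Built-in perfect detector stub
#'
#' Returns a detector function that emits exactly the truth record as a
#' single non-reference prediction, yielding recall = precision = 1 at
#' every window.
#'
#' @return A detector `function(ctx)` for [runBenchmark()].
#' @export
perfectDetector <- function() {
    function(ctx) {
        truth <- ctx$truth
        GenomicRanges::mcols(truth) <- S4Vectors::DataFrame(
            family = GenomicRanges::mcols(ctx$truth)$family,
            category = "non-reference", method = "perfect",
            sample = ctx$sample)
        truth
    }
}

#' Built-in noisy detector stub
#'
#' Returns a detector that misses the true insertion with probability
#' `pMiss`; when detected, both endpoints are shifted by one draw from
#' Normal(0, `shiftSd`) (rounded). `nSpurious` additional non-reference
#' calls with random position, family and strand are emitted per
#' replicate.
#'
#' @param pMiss Miss probability in `[0, 1]`.
#' @param shiftSd Standard deviation (bp) of the breakpoint shift.
#' @param nSpurious Number of spurious calls per replicate.
#' @return A detector `function(ctx)` for [runBenchmark()].
#' @export
noisyDetector <- function(pMiss = 0.5, shiftSd = 0, nSpurious = 0) {
    stopifnot(pMiss >= 0, pMiss <= 1, shiftSd >= 0, nSpurious >= 0)
    function(ctx) {
        chrom <- character(); s <- integer(); w <- integer()
        strand <- character(); fam <- character()
        if (runif(1) >= pMiss) {
            sh <- if (shiftSd > 0) as.integer(round(rnorm(1, 0, shiftSd)))
                  else 0L
            chrom <- as.character(GenomicRanges::seqnames(ctx$truth))
            s <- max(GenomicRanges::start(ctx$truth) + sh, 1L)
            w <- GenomicRanges::width(ctx$truth)
            strand <- as.character(GenomicRanges::strand(ctx$truth))
            fam <- GenomicRanges::mcols(ctx$truth)$family
        }
        if (nSpurious > 0) {
            lens <- setNames(Biostrings::width(ctx$reference),
                             names(ctx$reference))
            fams <- names(teConsensus(ctx$library))
            tw <- GenomicRanges::width(ctx$truth)
            for (k in seq_len(nSpurious)) {
                ch <- names(lens)[sample.int(length(lens), 1L)]
                chrom <- c(chrom, ch)
                s <- c(s, sample.int(max(lens[[ch]] - tw, 1L), 1L))
                w <- c(w, tw)
                strand <- c(strand, c("+", "-")[sample.int(2L, 1L)])
                fam <- c(fam, fams[sample.int(length(fams), 1L)])
            }
        }
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = s, width = w),
            strand = strand, family = fam,
            category = rep("non-reference", length(chrom)),
            method = rep("noisy", length(chrom)),
            sample = rep(ctx$sample, length(chrom)))
    }
}

#' Run the single-insertion benchmark end to end
#'
#' For each fold-coverage and replicate: plan an insertion, build the
#' synthetic genome, simulate a WGS read set from it, call the detector,
#' and tally the predictions against the truth; replicate tallies are then
#' aggregated into a precision/recall table across coverages. A detector
#' error is retried once; a replicate that fails twice is logged, counted,
#' and excluded from the metrics without affecting successful replicates.
#' All randomness flows from `config`'s master seed, so identical
#' (config, seed) yields identical metrics.
#'
#' @param genome Named [Biostrings::DNAStringSet] reference genome.
#' @param library [TELibrary-class].
#' @param sites `GRanges` of permissible insertion sites.
#' @param config [SimConfig-class].
#' @param detector `function(ctx)` returning a prediction `GRanges`;
#'   `ctx` carries `truth`, `synthetic`, `reference`, `library`,
#'   `readset`, `coverage`, `replicate`, `sample` and `seed`. See
#'   [perfectDetector()] and [noisyDetector()].
#' @param outDir Optional directory; when given, the metrics CSV and a
#'   run manifest (JSON) are written there.
#' @param simulateReadsFlag Set `FALSE` to skip read simulation (for
#'   detectors that do not consume reads); the default runs the full
#'   pipeline.
#' @param verbose Log one line per replicate.
#' @return A list with `metrics` (the long coverage x window table),
#'   `tallies` (per-coverage replicate tallies), `failures`
#'   (`data.frame` of failed replicates) and `manifest`.
#' @export
runBenchmark <- function(genome, library, sites, config = simConfig(),
                         detector = perfectDetector(), outDir = NULL,
                         simulateReadsFlag = TRUE, verbose = FALSE) {
    validObject(config)
    nCov <- length(config@coverages)
    nRep <- config@replicates
    seeds <- deriveSeeds(config@seed, nCov * nRep)
    tallies <- list()
    failures <- data.frame(coverage = numeric(), replicate = integer(),
                           error = character())
    k <- 0L
    for (ci in seq_len(nCov)) {
        cov <- config@coverages[ci]
        covTallies <- list()
        for (rep_ in seq_len(nRep)) {
            k <- k + 1L
            t0 <- proc.time()[["elapsed"]]
            res <- withSeed(seeds[k], {
                plan <- planInsertion(genome, library, sites, config)
                syn <- buildSyntheticGenome(genome, library, plan)
                rs <- if (simulateReadsFlag)
                    simulateReads(syn$genome, cov, config) else NULL
                ctx <- list(truth = syn$truth, synthetic = syn$genome,
                            reference = genome, library = library,
                            readset = rs, coverage = cov,
                            replicate = rep_, seed = seeds[k],
                            sample = sprintf("cov%g_rep%d", cov, rep_))
                preds <- tryCatch(detector(ctx), error = function(e) {
                    tryCatch(detector(ctx), error = function(e2) e2)
                })
                if (inherits(preds, "condition"))
                    list(ok = FALSE, error = conditionMessage(preds))
                else
                    list(ok = TRUE,
                         tally = tallyReplicate(syn$truth, preds,
                                                config@windows))
            })
            if (res$ok) {
                covTallies[[length(covTallies) + 1L]] <- res$tally
            } else {
                failures <- rbind(failures, data.frame(
                    coverage = cov, replicate = rep_, error = res$error))
            }
            if (verbose)
                message(sprintf(
                    "replicate=%d coverage=%g seed=%d stage=done elapsed=%.2fs outcome=%s",
                    rep_, cov, seeds[k],
                    proc.time()[["elapsed"]] - t0,
                    if (res$ok) "ok" else "failed"))
        }
        if (!length(covTallies))
            stopf("all replicates failed at coverage %g", cov)
        tallies[[as.character(cov)]] <- covTallies
    }
    metrics <- precisionRecallCurve(tallies)
    manifest <- list(
        tool = "tebench", version = as.character(utils::packageVersion("tebench")),
        seed = config@seed, replicates = nRep,
        coverages = config@coverages, windows = config@windows,
        tsd_len = config@tsdLen, read_len = config@readLen,
        paired = config@paired, error_rate = config@errorRate,
        n_failures = nrow(failures),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeMetricsCsv(metrics, file.path(outDir, "metrics.csv"))
        manifest$metrics_csv <- file.path(outDir, "metrics.csv")
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    list(metrics = metrics, tallies = tallies, failures = failures,
         manifest = manifest)
}
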