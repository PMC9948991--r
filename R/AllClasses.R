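#' @import methods
#' @importFrom stats median rnorm rpois runif rbinom setNames density cor
#' @importFrom utils head read.delim write.csv
NULL

# ---------------------------------------------------------------------------
# TELibrary
# ---------------------------------------------------------------------------

#' TE consensus library
#'
#' Holds the consensus sequence of each transposable element family, plus an
#' optional table of internal coding regions (the sub-interval of each
#' consensus covering internal coding sequence, used for full-length
#' copy-number estimation). Internal regions use 0-based half-open
#' coordinates along the consensus, matching the BED files they come from.
#'
#' @slot consensus A named [Biostrings::DNAStringSet] of family consensus
#'   sequences.
#' @slot internalRegions A `data.frame` with columns `family`, `start`,
#'   `end` (0-based half-open on the consensus); may have zero rows.
#'
#' @seealso [teLibrary()], [readTELibrary()], [teConsensus()],
#'   [internalRegions()]
#' @export
setClass("TELibrary",
    representation(consensus = "DNAStringSet", internalRegions = "data.frame"))

setValidity("TELibrary", function(object) {
    cons <- object@consensus
    nm <- names(cons)
    if (is.null(nm) || any(nm == "") || anyNA(nm))
        return("every consensus sequence must be named by its family")
    if (anyDuplicated(nm))
        return("duplicate family names in consensus library")
    if (any(Biostrings::width(cons) == 0L))
        return("empty consensus sequence")
    ir <- object@internalRegions
    need <- c("family", "start", "end")
    if (!all(need %in% colnames(ir)))
        return("internalRegions must have columns family, start, end")
    if (nrow(ir)) {
        if (!all(ir$family %in% nm))
            return("internalRegions refers to a family absent from the library")
        len <- setNames(Biostrings::width(cons), nm)[ir$family]
        if (any(ir$start < 0) || any(ir$end <= ir$start) || any(ir$end > len))
            return("internal region outside [0, consensus length)")
    }
    TRUE
})

#' Construct a TE library
#'
#' @param consensus Named [Biostrings::DNAStringSet] (or named character
#'   vector) of family consensus sequences.
#' @param internalRegions Optional `data.frame` with columns `family`,
#'   `start`, `end` (0-based half-open sub-interval of the consensus marking
#'   the internal coding sequence).
#' @return A [TELibrary-class] object.
#' @examples
#' lib <- teLibrary(c(TY1 = "ACGTACGTAC", TY2 = "GGGGCCCC"))
#' teConsensus(lib)
#' @export
teLibrary <- function(consensus, internalRegions = NULL) {
    if (is.character(consensus))
        consensus <- Biostrings::DNAStringSet(toupper(consensus))
    if (is.null(internalRegions))
        internalRegions <- data.frame(family = character(), start = integer(),
                                      end = integer())
    new("TELibrary", consensus = consensus,
        internalRegions = as.data.frame(internalRegions))
}

#' @describeIn teLibrary Family consensus sequences as a `DNAStringSet`.
#' @param x A `TELibrary`.
#' @export
teConsensus <- function(x) x@consensus

#' @describeIn teLibrary Internal coding regions table (0-based half-open).
#' @export
internalRegions <- function(x) x@internalRegions

setMethod("show", "TELibrary", function(object) {
    cat("TELibrary with", length(object@consensus), "families:",
        paste(names(object@consensus), collapse = ", "), "\n")
    if (nrow(object@internalRegions))
        cat("  internal regions defined for",
            nrow(object@internalRegions), "families\n")
})

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' All knobs of a single-synthetic-insertion benchmark experiment: replicate
#' count, TSD length and strand policy of the insertion, WGS read
#' properties, the fold-coverage grid, and the within-N window sizes used
#' for scoring. Defaults reflect the yeast evaluation conditions: 5-bp TSDs,
#' 101-bp paired-end reads, fold-coverages 3, 6, 12, 25, 50, 100 and
#' windows 0, 5, 100, 300, 500.
#'
#' @seealso [simConfig()], [loadConfig()]
#' @export
setClass("SimConfig", representation(
    replicates   = "integer",
    tsdLen       = "integer",
    strandPolicy = "character",
    familyPolicy = "ANY",
    readLen      = "integer",
    paired       = "logical",
    insertMean   = "numeric",
    insertSd     = "numeric",
    errorRate    = "numeric",
    coverages    = "numeric",
    simulator    = "character",
    seed         = "integer",
    windows      = "integer",
    paths        = "list"))

setValidity("SimConfig", function(object) {
    msg <- character()
    chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
    chk(object@replicates >= 1L, "replicates must be >= 1")
    chk(object@tsdLen >= 0L, "tsd_len must be >= 0")
    chk(object@strandPolicy %in% c("random", "fixed+", "fixed-"),
        "strand_policy must be one of random, fixed+, fixed-")
    fp <- object@familyPolicy
    chk(identical(fp, "uniform") ||
        (is.numeric(fp) && length(fp) > 0 && !is.null(names(fp)) &&
         all(fp >= 0) && sum(fp) > 0),
        "family_policy must be \"uniform\" or a named non-negative weight table")
    chk(object@readLen >= 1L, "read_len must be >= 1")
    chk(object@insertMean >= 0, "insert_mean must be >= 0")
    chk(object@insertSd >= 0, "insert_sd must be >= 0")
    chk(object@errorRate >= 0 && object@errorRate <= 1,
        "error_rate must lie in [0, 1]")
    chk(length(object@coverages) > 0, "coverages must be non-empty")
    chk(all(object@coverages > 0), "coverages must be positive")
    chk(object@simulator %in% c("builtin", "art", "wgsim"),
        "simulator must be one of builtin, art, wgsim")
    chk(length(object@windows) > 0, "windows must be non-empty")
    chk(all(object@windows >= 0L), "windows must be >= 0")
    chk(!is.unsorted(object@windows, strictly = FALSE),
        "windows must be sorted ascending")
    if (object@paired)
        chk(object@insertMean >= object@readLen,
            "insert_mean must be >= read_len for paired-end reads")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param replicates Number of replicate synthetic genomes per coverage.
#' @param tsdLen Target-site duplication length in bp (5 for yeast Ty).
#' @param strandPolicy `"random"` (each strand with probability 1/2),
#'   `"fixed+"` or `"fixed-"`.
#' @param familyPolicy `"uniform"` over the library, or a named numeric
#'   vector of family weights.
#' @param readLen Read length in bp.
#' @param paired Paired-end (`TRUE`) or single-end (`FALSE`) reads.
#' @param insertMean,insertSd Fragment (insert) size distribution in bp for
#'   paired-end reads; Normal, truncated to fit the chromosome.
#' @param errorRate Per-base substitution error probability.
#' @param coverages Fold-coverage grid.
#' @param simulator Read simulator; only `"builtin"` executes in this
#'   package.
#' @param seed Master seed; all randomness in a benchmark flows from it.
#' @param windows Within-N window sizes (bp), sorted ascending.
#' @param paths Optional named list of input paths (genome, library, sites,
#'   taxonomy, out_dir) carried along from a JSON config.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(replicates = 5, coverages = c(10, 25))
#' cfg
#' @export
simConfig <- function(replicates = 30L, tsdLen = 5L, strandPolicy = "random",
                      familyPolicy = "uniform", readLen = 101L, paired = TRUE,
                      insertMean = 300, insertSd = 50, errorRate = 0.001,
                      coverages = c(3, 6, 12, 25, 50, 100),
                      simulator = "builtin", seed = 1L,
                      windows = c(0L, 5L, 100L, 300L, 500L),
                      paths = list()) {
    new("SimConfig",
        replicates = as.integer(replicates), tsdLen = as.integer(tsdLen),
        strandPolicy = strandPolicy, familyPolicy = familyPolicy,
        readLen = as.integer(readLen), paired = isTRUE(paired),
        insertMean = as.numeric(insertMean), insertSd = as.numeric(insertSd),
        errorRate = as.numeric(errorRate), coverages = as.numeric(coverages),
        simulator = simulator, seed = as.integer(seed),
        windows = as.integer(windows), paths = paths)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@replicates, "replicates,",
        if (object@paired) "paired-end" else "single-end",
        paste0(object@readLen, "-bp reads, TSD ", object@tsdLen, " bp\n"))
    cat("  coverages:", paste(object@coverages, collapse = ", "), "\n")
    cat("  windows:  ", paste(object@windows, collapse = ", "), "\n")
    cat("  error rate", object@errorRate, "| seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# InsertionPlan
# ---------------------------------------------------------------------------

#' A planned synthetic insertion
#'
#' Where and what to insert: chromosome, 0-based breakpoint, family, strand
#' and TSD length. Produced by [planInsertion()] and consumed by
#' [buildSyntheticGenome()].
#'
#' @slot chrom Chromosome name.
#' @slot breakpoint 0-based position; the TSD is the `tsdLen` reference
#'   bases starting at the breakpoint.
#' @slot family TE family (must exist in the library).
#' @slot strand `"+"` or `"-"`.
#' @slot tsdLen TSD length in bp.
#' @export
setClass("InsertionPlan", representation(
    chrom = "character", breakpoint = "integer", family = "character",
    strand = "character", tsdLen = "integer"))

setValidity("InsertionPlan", function(object) {
    if (!isScalarString(object@chrom) || !nzchar(object@chrom))
        return("chrom must be a non-empty string")
    if (object@breakpoint < 0L) return("breakpoint must be >= 0")
    if (!object@strand %in% c("+", "-")) return("strand must be + or -")
    if (object@tsdLen < 0L) return("tsdLen must be >= 0")
    TRUE
})

insertionPlan <- function(chrom, breakpoint, family, strand, tsdLen) {
    new("InsertionPlan", chrom = chrom, breakpoint = as.integer(breakpoint),
        family = family, strand = strand, tsdLen = as.integer(tsdLen))
}

setMethod("show", "InsertionPlan", function(object) {
    cat(sprintf("InsertionPlan: %s(%s) at %s:%d (0-based), TSD %d bp\n",
                object@family, object@strand, object@chrom,
                object@breakpoint, object@tsdLen))
})

# ---------------------------------------------------------------------------
# ReadSet
# ---------------------------------------------------------------------------

#' A simulated WGS read set
#'
#' Mate-aware container for simulated reads. For paired-end data `mate1`
#' and `mate2` have equal length and matched ids; for single-end data
#' `mate2` is empty. The `layout` metadata records the genomic origin of
#' every fragment so depth can be recomputed independently of the
#' sequences.
#'
#' @slot mate1,mate2 [Biostrings::DNAStringSet] of read sequences, names =
#'   read ids.
#' @slot paired Logical flag.
#' @slot readLen Read length (bp); constant across the set.
#' @slot qualityChar Single character used as the constant base quality.
#' @slot metadata List of provenance (genome id, seed, coverage, fragment
#'   layout).
#' @seealso [simulateReads()], [downsampleReads()], [writeReadSet()]
#' @export
setClass("ReadSet", representation(
    mate1 = "DNAStringSet", mate2 = "DNAStringSet", paired = "logical",
    readLen = "integer", qualityChar = "character", metadata = "list"))

setValidity("ReadSet", function(object) {
    if (object@paired && length(object@mate1) != length(object@mate2))
        return("paired read set with unequal mate counts")
    if (!object@paired && length(object@mate2) != 0L)
        return("single-end read set must have empty mate2")
    w <- c(Biostrings::width(object@mate1), Biostrings::width(object@mate2))
    if (length(w) && any(w != object@readLen))
        return("all read lengths must equal readLen")
    if (nchar(object@qualityChar) != 1L)
        return("qualityChar must be a single character")
    TRUE
})

#' @describeIn ReadSet Number of fragments (pairs, or reads if single-end).
#' @param x A `ReadSet`.
#' @export
nFragments <- function(x) length(x@mate1)

#' @describeIn ReadSet First-mate sequences.
#' @export
mate1 <- function(x) x@mate1

#' @describeIn ReadSet Second-mate sequences (empty when single-end).
#' @export
mate2 <- function(x) x@mate2

setMethod("show", "ReadSet", function(object) {
    cat(sprintf("ReadSet: %d %s of %d-bp reads (coverage %s, seed %s)\n",
                length(object@mate1),
                if (object@paired) "pairs" else "single-end reads",
                object@readLen,
                format(object@metadata$coverage %||% NA),
                format(object@metadata$seed %||% NA)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
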