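# The generative half of the benchmark: plan a single TE insertion, build
# the synthetic genome carrying it (with its target-site duplication),
# simulate WGS reads, and down-sample read sets.

# ---------------------------------------------------------------------------
# Insertion planning
# ---------------------------------------------------------------------------

#' Plan a single synthetic TE insertion
#'
#' Draws the family (per the family policy; uniform over the library by
#' default), an insertion-site interval with probability proportional to
#' its width, a breakpoint uniform within that interval, and a strand per
#' the strand policy (each of +/- with probability 1/2 by default).
#' Deterministic given `seed`.
#'
#' @param genome Named [Biostrings::DNAStringSet] reference genome.
#' @param library [TELibrary-class].
#' @param sites `GRanges` of permissible insertion-site intervals.
#' @param config [SimConfig-class] supplying `tsdLen` and the policies;
#'   individual arguments below override it.
#' @param tsdLen,strandPolicy,familyPolicy See [simConfig()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An [InsertionPlan-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrI = strrep("ACGT", 50)))
#' lib <- teLibrary(c(TY1 = "TTTTGGGG"))
#' sites <- GenomicRanges::GRanges("chrI", IRanges::IRanges(51, 150))
#' planInsertion(g, lib, sites, seed = 1)
#' @export
planInsertion <- function(genome, library, sites, config = NULL,
                          tsdLen = NULL, strandPolicy = NULL,
                          familyPolicy = NULL, seed = NULL) {
    if (is.null(config)) config <- simConfig()
    tsdLen <- as.integer(tsdLen %||% config@tsdLen)
    strandPolicy <- strandPolicy %||% config@strandPolicy
    familyPolicy <- familyPolicy %||% config@familyPolicy
    if (length(sites) == 0L)
        stopf("empty insertion-site list")
    if (any(GenomicRanges::width(sites) < 1L))
        stopf("insertion site narrower than 1 bp")
    lens <- setNames(Biostrings::width(genome), names(genome))
    chroms <- as.character(GenomicRanges::seqnames(sites))
    if (!all(chroms %in% names(lens)))
        stopf("site chromosome absent from genome: %s",
              paste(setdiff(chroms, names(lens)), collapse = ", "))
    if (any(GenomicRanges::end(sites) > lens[chroms]))
        stopf("insertion site extends beyond its chromosome")
    withSeed(seed, {
        fams <- names(teConsensus(library))
        if (identical(familyPolicy, "uniform")) {
            family <- fams[sample.int(length(fams), 1L)]
        } else {
            w <- familyPolicy[fams]
            w[is.na(w)] <- 0
            if (sum(w) <= 0)
                stopf("family weights assign no mass to any library family")
            family <- fams[sample.int(length(fams), 1L, prob = w)]
        }
        wdt <- GenomicRanges::width(sites)
        si <- sample.int(length(sites), 1L, prob = wdt)
        # breakpoint: 0-based, uniform over the chosen interval
        lo <- GenomicRanges::start(sites)[si] - 1L
        p0 <- lo + sample.int(wdt[si], 1L) - 1L
        strand <- switch(strandPolicy,
            "random" = c("+", "-")[sample.int(2L, 1L)],
            "fixed+" = "+", "fixed-" = "-")
        L <- lens[[chroms[si]]]
        if (p0 + tsdLen > L)
            stopf("breakpoint %d + TSD %d exceeds length of %s (%d)",
                  p0, tsdLen, chroms[si], L)
        insertionPlan(chroms[si], p0, family, strand, tsdLen)
    })
}

# ---------------------------------------------------------------------------
# Synthetic genome construction
# ---------------------------------------------------------------------------

#' Build a synthetic genome with one TE insertion
#'
#' Inserts the family consensus (reverse-complemented for minus-strand
#' plans) at the planned breakpoint, duplicating the `tsdLen` reference
#' bases starting at the breakpoint on both flanks: with `D = ref[p,
#' p+tsd)`, the synthetic chromosome is `ref[0, p+tsd) + TE + ref[p, L)`,
#' so the TE ends up flanked by two copies of `D` and the new length is
#' `L + |TE| + tsd`.
#'
#' @param genome Named [Biostrings::DNAStringSet] reference genome.
#' @param library [TELibrary-class].
#' @param plan [InsertionPlan-class].
#' @return A list with elements `genome` (the synthetic
#'   `DNAStringSet`) and `truth` (a one-record `GRanges` over the TSD
#'   interval in *reference* coordinates, with metadata `family` and
#'   `tsdLen` and the insertion strand).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrI = "ACGTACGTAC"))
#' lib <- teLibrary(c(TY1 = "TTTT"))
#' syn <- buildSyntheticGenome(g, lib, tebench:::insertionPlan(
#'     "chrI", 4L, "TY1", "+", 2L))
#' as.character(syn$genome$chrI)  # "ACGTACTTTTACGTAC"
#' @export
buildSyntheticGenome <- function(genome, library, plan) {
    validObject(plan)
    if (!plan@chrom %in% names(genome))
        stopf("plan chromosome %s absent from genome", plan@chrom)
    cons <- teConsensus(library)
    if (!plan@family %in% names(cons))
        stopf("family %s absent from library", plan@family)
    chromSeq <- genome[[plan@chrom]]
    L <- length(chromSeq)
    p <- plan@breakpoint
    tsd <- plan@tsdLen
    if (p + tsd > L)
        stopf("breakpoint + TSD exceeds chromosome length")
    te <- cons[[plan@family]]
    if (plan@strand == "-")
        te <- Biostrings::reverseComplement(te)
    left <- if (p + tsd > 0L) Biostrings::subseq(chromSeq, 1L, p + tsd)
            else Biostrings::DNAString("")
    right <- if (p < L) Biostrings::subseq(chromSeq, p + 1L, L)
             else Biostrings::DNAString("")
    newSeq <- Biostrings::xscat(left, te, right)
    seqs <- as.character(genome)
    seqs[[plan@chrom]] <- as.character(newSeq)
    synthetic <- Biostrings::DNAStringSet(seqs)
    truth <- GenomicRanges::GRanges(plan@chrom,
        IRanges::IRanges(start = p + 1L, width = tsd),
        strand = plan@strand, family = plan@family, tsdLen = tsd)
    list(genome = synthetic, truth = truth)
}

# ---------------------------------------------------------------------------
# Read simulation
# ---------------------------------------------------------------------------

# Truncated-normal fragment lengths by rejection; redraws out-of-range
# values up to `maxAttempts` rounds, then errors (avoids silent bias on
# tiny chromosomes).
drawFragmentLengths <- function(n, mean, sd, lo, hi, maxAttempts = 1000L) {
    frag <- round(rnorm(n, mean, sd))
    for (i in seq_len(maxAttempts)) {
        bad <- which(frag < lo | frag > hi)
        if (!length(bad)) return(as.integer(frag))
        frag[bad] <- round(rnorm(length(bad), mean, sd))
    }
    stopf("could not draw fragment lengths in [%d, %d] after %d attempts",
          lo, hi, maxAttempts)
}

# Substitute each base with probability `rate` to a uniformly chosen
# different base. Operates on a character vector of equal-length reads.
injectErrors <- function(reads, readLen, rate) {
    if (rate <= 0 || !length(reads)) return(reads)
    nTotal <- length(reads) * readLen
    k <- rbinom(1L, nTotal, rate)
    if (k == 0L) return(reads)
    idx <- sort(sample.int(nTotal, k))
    ri <- (idx - 1L) %/% readLen + 1L
    pos <- (idx - 1L) %% readLen + 1L
    pick <- runif(k)
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(k)) {
        cur <- substr(reads[ri[j]], pos[j], pos[j])
        alt <- bases[bases != cur]
        if (length(alt) == 3L) {
            newBase <- alt[ceiling(pick[j] * 3)]
        } else {                      # N or other: any of the four
            newBase <- bases[ceiling(pick[j] * 4)]
        }
        substr(reads[ri[j]], pos[j], pos[j]) <- newBase
    }
    reads
}

#' Simulate a WGS read set from a genome
#'
#' For each chromosome of length `L`, `round(coverage * L / (2 *
#' readLen))` fragment pairs are drawn (or `round(coverage * L /
#' readLen)` single reads). Fragment lengths are Normal(`insertMean`,
#' `insertSd`) truncated to `[readLen, L]`; fragment starts are uniform
#' such that the fragment fits. Mate 1 is the forward strand of the
#' fragment's 5' end; mate 2 is the reverse complement of its 3' end.
#' Each base is substituted with probability `errorRate` to a uniformly
#' chosen different base; base qualities are a constant symbol.
#' Deterministic given `seed`.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param coverage Fold-coverage (> 0).
#' @param config Optional [SimConfig-class] supplying read parameters;
#'   individual arguments override it.
#' @param readLen,paired,insertMean,insertSd,errorRate See [simConfig()].
#' @param qualityChar Constant FASTQ quality symbol.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A [ReadSet-class]; `metadata(rs)$layout` records each
#'   fragment's chromosome, start and length so depth can be recomputed
#'   independently of the sequences.
#' @export
simulateReads <- function(genome, coverage, config = NULL, readLen = NULL,
                          paired = NULL, insertMean = NULL, insertSd = NULL,
                          errorRate = NULL, qualityChar = "I", seed = NULL) {
    if (is.null(config)) config <- simConfig()
    if (config@simulator != "builtin")
        stopf("read simulator '%s' is not available; use simulator = \"builtin\"",
              config@simulator)
    readLen <- as.integer(readLen %||% config@readLen)
    paired <- paired %||% config@paired
    insertMean <- insertMean %||% config@insertMean
    insertSd <- insertSd %||% config@insertSd
    errorRate <- errorRate %||% config@errorRate
    if (coverage <= 0) stopf("coverage must be > 0")
    lens <- setNames(Biostrings::width(genome), names(genome))
    if (any(readLen > lens))
        stopf("read_len %d exceeds length of chromosome(s): %s", readLen,
              paste(names(lens)[readLen > lens], collapse = ", "))
    if (paired && insertMean < readLen)
        stopf("insert_mean must be >= read_len for paired-end simulation")
    withSeed(seed, {
        m1 <- character(); m2 <- character()
        layChrom <- character(); layStart <- integer(); layFrag <- integer()
        ids <- character()
        for (ch in names(genome)) {
            L <- lens[[ch]]
            chromStr <- as.character(genome[[ch]])
            if (paired) {
                n <- round(coverage * L / (2 * readLen))
                if (n < 1L) next
                frag <- drawFragmentLengths(n, insertMean, insertSd,
                                            readLen, L)
                start <- floor(runif(n) * (L - frag + 1)) + 1L
                r1 <- substring(chromStr, start, start + readLen - 1L)
                e2 <- start + frag - 1L
                r2fwd <- substring(chromStr, e2 - readLen + 1L, e2)
                r2 <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(r2fwd)))
                m1 <- c(m1, r1); m2 <- c(m2, r2)
            } else {
                n <- round(coverage * L / readLen)
                if (n < 1L) next
                frag <- rep(readLen, n)
                start <- floor(runif(n) * (L - readLen + 1)) + 1L
                m1 <- c(m1, substring(chromStr, start, start + readLen - 1L))
            }
            layChrom <- c(layChrom, rep(ch, n))
            layStart <- c(layStart, as.integer(start))
            layFrag <- c(layFrag, as.integer(frag))
            ids <- c(ids, sprintf("sim.%s.%d", ch, seq_len(n)))
        }
        m1 <- injectErrors(m1, readLen, errorRate)
        if (paired) m2 <- injectErrors(m2, readLen, errorRate)
        mate1 <- Biostrings::DNAStringSet(m1); names(mate1) <- ids
        mate2 <- Biostrings::DNAStringSet(m2)
        if (paired) names(mate2) <- ids
        new("ReadSet", mate1 = mate1, mate2 = mate2, paired = isTRUE(paired),
            readLen = readLen, qualityChar = qualityChar,
            metadata = list(
                genomeId = paste(names(genome), collapse = ","),
                coverage = coverage, seed = seed, errorRate = errorRate,
                layout = data.frame(chrom = layChrom, start = layStart,
                                    fragLen = layFrag)))
    })
}

#' Down-sample a read set to a target fold-coverage
#'
#' Keeps each pair (or single read) independently with probability
#' `targetCov / currentCov`, mates kept or dropped together; a target at
#' or above the current coverage returns the input unchanged.
#' Deterministic given `seed`.
#'
#' @param readset A [ReadSet-class].
#' @param currentCov,targetCov Fold-coverages (> 0).
#' @param seed Integer seed, or `NULL`.
#' @return A [ReadSet-class].
#' @export
downsampleReads <- function(readset, currentCov, targetCov, seed = NULL) {
    if (currentCov <= 0) stopf("current coverage must be > 0")
    if (targetCov <= 0) stopf("target coverage must be > 0")
    if (targetCov >= currentCov) return(readset)
    withSeed(seed, {
        n <- nFragments(readset)
        keep <- runif(n) < targetCov / currentCov
        out <- readset
        out@mate1 <- readset@mate1[keep]
        if (readset@paired) out@mate2 <- readset@mate2[keep]
        out@metadata$coverage <- targetCov
        if (!is.null(out@metadata$layout))
            out@metadata$layout <- readset@metadata$layout[keep, ,
                                                           drop = FALSE]
        out
    })
}

#' Write a read set as FASTQ
#'
#' Paired sets produce `<prefix>_1.fastq` and `<prefix>_2.fastq` with read
#' ids suffixed `/1` and `/2`; single-end sets produce
#' `<prefix>_1.fastq`. Base qualities are the set's constant symbol.
#'
#' @param readset A [ReadSet-class].
#' @param prefix Output path prefix.
#' @return Character vector of the file(s) written, invisibly.
#' @export
writeReadSet <- function(readset, prefix) {
    writeOne <- function(seqs, suffix, mateTag) {
        path <- paste0(prefix, suffix)
        x <- seqs
        names(x) <- paste0(names(seqs), "/", mateTag)
        qual <- Biostrings::BStringSet(strrep(readset@qualityChar,
                                              Biostrings::width(x)))
        Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                    qualities = qual)
        path
    }
    files <- writeOne(readset@mate1, "_1.fastq", "1")
    if (readset@paired)
        files <- c(files, writeOne(readset@mate2, "_2.fastq", "2"))
    invisible(files)
}

#' Recompute per-base depth from a read set's fragment layout
#'
#' Stacks the read intervals recorded in the layout metadata (both mates
#' for paired data) into a per-base depth track, independent of the read
#' sequences. Used to verify the simulator's coverage contract.
#'
#' @param readset A [ReadSet-class] with layout metadata.
#' @param seqlengths Named vector of chromosome lengths.
#' @return A per-base depth track (list of numeric `Rle` per chromosome).
#' @export
readDepthTrack <- function(readset, seqlengths) {
    lay <- readset@metadata$layout
    if (is.null(lay))
        stopf("read set has no layout metadata")
    rl <- readset@readLen
    if (readset@paired) {
        gr <- GenomicRanges::GRanges(rep(lay$chrom, 2L), IRanges::IRanges(
            start = c(lay$start, lay$start + lay$fragLen - rl),
            width = rl))
    } else {
        gr <- GenomicRanges::GRanges(lay$chrom,
            IRanges::IRanges(start = lay$start, width = rl))
    }
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    cov <- GenomicRanges::coverage(gr)
    out <- lapply(names(seqlengths), function(ch)
        S4Vectors::Rle(as.numeric(cov[[ch]])))
    names(out) <- names(seqlengths)
    S4Vectors::SimpleList(out)
}
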