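# Readers and writers for the standard formats the toolkit touches:
# FASTA, BED6, VCF 4.2, bedGraph / fixed-step wiggle, taxonomy TSV, JSON
# config. Coordinates are 0-based half-open in every BED-like file and
# 1-based in VCF and GRanges; conversion happens only at these boundaries.

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a genome or sequence set from FASTA
#'
#' Sequences are uppercased, record order is preserved, and the header
#' token before the first whitespace becomes the sequence name. The
#' alphabet is restricted to A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chrI", "acgtn"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path))
        stopf("file not found: %s", path)
    x <- tryCatch(Biostrings::readDNAStringSet(path),
        error = function(e)
            stopf("not valid FASTA (%s): %s", path, conditionMessage(e)))
    if (length(x) == 0L)
        stopf("no FASTA records in %s", path)
    nm <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(nm))
        stopf("duplicate sequence name(s): %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
    if (any(Biostrings::width(x) == 0L))
        stopf("empty sequence: %s", paste(nm[Biostrings::width(x) == 0L],
                                          collapse = ", "))
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    names(x) <- nm
    bad <- Biostrings::letterFrequency(x, letters = "ACGTN")
    if (any(bad != Biostrings::width(x)))
        stopf("sequence alphabet outside {A,C,G,T,N} in: %s",
              paste(nm[bad != Biostrings::width(x)], collapse = ", "))
    x
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path) {
    if (is.character(x))
        x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, filepath = path, width = 70L)
    invisible(path)
}

#' Read a TE consensus library
#'
#' @param path FASTA of family consensus sequences (names = families).
#' @param internalRegions Optional BED path whose first column is the
#'   family name and whose start/end give the internal coding region on the
#'   consensus (0-based half-open).
#' @return A [TELibrary-class].
#' @export
readTELibrary <- function(path, internalRegions = NULL) {
    cons <- readGenome(path)
    ir <- NULL
    if (!is.null(internalRegions)) {
        gr <- readBed(internalRegions)
        ir <- data.frame(family = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr))
    }
    teLibrary(cons, ir)
}

#' Read a taxonomy table mapping reference TE copies to families
#'
#' @param path Two-column tab-separated file: TE copy id, family name.
#' @param library Optional [TELibrary-class]; when given, every family in
#'   the table must exist in the library.
#' @return A `data.frame` with columns `te_copy_id`, `family`.
#' @export
readTaxonomy <- function(path, library = NULL) {
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character", comment.char = "#")
    if (ncol(tab) < 2L)
        stopf("taxonomy file must have two tab-separated columns: %s", path)
    tab <- data.frame(te_copy_id = tab[[1L]], family = tab[[2L]])
    if (anyDuplicated(tab$te_copy_id))
        stopf("duplicate TE copy id(s) in taxonomy: %s",
              paste(unique(tab$te_copy_id[duplicated(tab$te_copy_id)]),
                    collapse = ", "))
    if (!is.null(library)) {
        miss <- setdiff(tab$family, names(teConsensus(library)))
        if (length(miss))
            stopf("taxonomy families absent from library: %s",
                  paste(miss, collapse = ", "))
    }
    tab
}

# ---------------------------------------------------------------------------
# BED
# ---------------------------------------------------------------------------

#' Read a BED file into a GRanges
#'
#' Accepts >= 3 tab-separated columns; `track`, `browser` and `#` lines are
#' skipped. Coordinates are converted from BED 0-based half-open to the
#' 1-based closed convention of [GenomicRanges::GRanges]; a BED end equals
#' the GRanges end. Missing strand (absent column or `"."`) is preserved as
#' `"*"`.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` with metadata columns `name` and `score`.
#' @export
readBed <- function(path) {
    if (!file.exists(path))
        stopf("file not found: %s", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GenomicRanges::GRanges()
        GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(name = character(),
                                                         score = numeric())
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 3L))
        stopf("line %d: fewer than 3 tab-separated columns",
              lineNo[which(ncols < 3L)[1L]])
    getCol <- function(i, default = NA_character_)
        vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
    chrom <- getCol(1L)
    start0 <- suppressWarnings(as.numeric(getCol(2L)))
    end0 <- suppressWarnings(as.numeric(getCol(3L)))
    badNum <- is.na(start0) | is.na(end0) | start0 != floor(start0) |
        end0 != floor(end0)
    if (any(badNum))
        stopf("line %d: non-integer coordinate", lineNo[which(badNum)[1L]])
    if (any(start0 < 0))
        stopf("line %d: negative start", lineNo[which(start0 < 0)[1L]])
    if (any(start0 > end0))
        stopf("line %d: start > end", lineNo[which(start0 > end0)[1L]])
    name <- getCol(4L); name[is.na(name)] <- "."
    score <- suppressWarnings(as.numeric(getCol(5L))); score[is.na(score)] <- 0
    strand <- getCol(6L); strand[is.na(strand)] <- "."
    bad <- !strand %in% c("+", "-", ".")
    if (any(bad))
        stopf("line %d: invalid strand %s", lineNo[which(bad)[1L]],
              strand[which(bad)[1L]])
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1, end = end0),
        strand = strandFromBed(strand), name = name, score = score)
}

#' Write a GRanges to BED6
#'
#' The inverse of [readBed()]: GRanges 1-based closed coordinates become
#' BED 0-based half-open; `"*"` strand is written as `"."`. `name` and
#' `score` metadata columns are used when present.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    mc <- GenomicRanges::mcols(gr)
    name <- if ("name" %in% colnames(mc)) as.character(mc$name)
            else rep(".", length(gr))
    score <- if ("score" %in% colnames(mc)) as.numeric(mc$score)
             else rep(0, length(gr))
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = format(GenomicRanges::start(gr) - 1L, scientific = FALSE,
                       trim = TRUE),
        end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
        name = name, score = score,
        strand = strandToBed(GenomicRanges::strand(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# Prediction name grammar: "FAMILY|CATEGORY|METHOD" (canonical), with a
# fallback accepting "FAMILY_non-reference"-style names.
parsePredictionName <- function(name, method = NA_character_) {
    parts <- strsplit(name, "|", fixed = TRUE)
    family <- character(length(name))
    category <- character(length(name))
    meth <- rep(method, length.out = length(name))
    for (i in seq_along(parts)) {
        p <- parts[[i]]
        if (length(p) >= 2L && p[2L] %in% c("reference", "non-reference")) {
            family[i] <- p[1L]
            category[i] <- p[2L]
            if (length(p) >= 3L && is.na(meth[i])) meth[i] <- p[3L]
        } else if (grepl("_(non-)?reference$", name[i])) {
            category[i] <- sub("^.*_((non-)?reference)$", "\\1", name[i])
            family[i] <- sub("_(non-)?reference$", "", name[i])
        } else {
            stopf("cannot parse prediction name %s (expected FAMILY|CATEGORY|METHOD)",
                  name[i])
        }
    }
    meth[is.na(meth)] <- "unknown"
    data.frame(family = family, category = category, method = meth)
}

#' Read detector predictions from a BED file
#'
#' The BED name field is parsed as `FAMILY|CATEGORY|METHOD` (with
#' `FAMILY_non-reference`-style names accepted as a fallback), yielding one
#' prediction per record.
#'
#' @param path BED path.
#' @param sample Sample/strain label attached to every prediction.
#' @param method Detector name; overrides nothing if the name field already
#'   carries one (`NA` = take from the name field).
#' @return A `GRanges` with metadata columns `family`, `category`,
#'   `method`, `sample`.
#' @export
readPredictions <- function(path, sample = "", method = NA_character_) {
    gr <- readBed(path)
    if (!length(gr)) {
        mc <- S4Vectors::DataFrame(family = character(),
            category = character(), method = character(),
            sample = character())
        GenomicRanges::mcols(gr) <- mc
        return(gr)
    }
    info <- parsePredictionName(GenomicRanges::mcols(gr)$name, method)
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
        family = info$family, category = info$category, method = info$method,
        sample = rep(sample, length(gr)))
    gr
}

#' Write predictions to BED6
#'
#' Names are encoded as `FAMILY|CATEGORY|METHOD` so that
#' [readPredictions()] round-trips.
#'
#' @param predictions `GRanges` with `family`, `category`, `method`
#'   metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(predictions, path) {
    mc <- GenomicRanges::mcols(predictions)
    gr <- predictions
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
        name = paste(mc$family, mc$category, mc$method, sep = "|"),
        score = 0)
    writeBed(gr, path)
}

#' Write a truth record to BED6
#'
#' Name = family, strand column set; coordinates are the TSD interval in
#' reference coordinates.
#'
#' @param truth Truth `GRanges` from [buildSyntheticGenome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(truth, path) {
    gr <- truth
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
        name = GenomicRanges::mcols(truth)$family, score = 0)
    writeBed(gr, path)
}

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

#' Write non-reference predictions as VCF 4.2
#'
#' One record per prediction with a symbolic insertion allele
#' `<INS:ME:FAMILY>`. POS is the 1-based position of the interval start
#' (BED start + 1), REF is the reference base at POS, and INFO carries the
#' family, strand, detector and END (the 1-based inclusive interval end).
#'
#' @param predictions `GRanges` of non-reference predictions (metadata
#'   `family`, `category`, `method`).
#' @param genome Named [Biostrings::DNAStringSet] providing REF bases.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVcf <- function(predictions, genome, path) {
    mc <- GenomicRanges::mcols(predictions)
    if (length(predictions) && any(mc$category != "non-reference"))
        stopf("writeVcf expects non-reference predictions only")
    chroms <- as.character(GenomicRanges::seqnames(predictions))
    miss <- setdiff(unique(chroms), names(genome))
    if (length(miss))
        stopf("prediction chromosome(s) absent from genome: %s",
              paste(miss, collapse = ", "))
    hdr <- c("##fileformat=VCFv4.2",
        "##source=tebench",
        paste0("##contig=<ID=", names(genome), ",length=",
               Biostrings::width(genome), ">"),
        "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
        "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"TE family\">",
        "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Insertion strand\">",
        "##INFO=<ID=METHOD,Number=1,Type=String,Description=\"Detector\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Interval end (1-based inclusive)\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    if (!length(predictions)) {
        writeLines(hdr, path)
        return(invisible(path))
    }
    pos <- GenomicRanges::start(predictions)
    L <- setNames(Biostrings::width(genome), names(genome))[chroms]
    if (any(pos > L))
        stopf("prediction POS beyond chromosome end")
    ref <- vapply(seq_along(predictions), function(i)
        as.character(Biostrings::subseq(genome[[chroms[i]]], pos[i], pos[i])),
        "")
    info <- sprintf("SVTYPE=INS;FAMILY=%s;STRAND=%s;METHOD=%s;END=%d",
                    mc$family,
                    strandToBed(GenomicRanges::strand(predictions)),
                    mc$method, GenomicRanges::end(predictions))
    recs <- sprintf("%s\t%d\t.\t%s\t<INS:ME:%s>\t.\t.\t%s",
                    chroms, pos, ref, mc$family, info)
    writeLines(c(hdr, recs), path)
    invisible(path)
}

#' Read predictions back from a tebench VCF
#'
#' Parses the VCF 4.2 files produced by [writeVcf()] (symbolic
#' `<INS:ME:FAMILY>` records) back into a prediction `GRanges`.
#'
#' @param path VCF path.
#' @param sample Sample label to attach.
#' @return A `GRanges` with `family`, `category`, `method`, `sample`.
#' @export
readVcfPredictions <- function(path, sample = "") {
    lines <- readLines(path)
    recs <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(recs)) {
        gr <- GenomicRanges::GRanges()
        GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
            family = character(), category = character(),
            method = character(), sample = character())
        return(gr)
    }
    f <- strsplit(recs, "\t", fixed = TRUE)
    getInfo <- function(info, key) {
        m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
        vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
    }
    chrom <- vapply(f, `[`, "", 1L)
    pos <- as.integer(vapply(f, `[`, "", 2L))
    info <- vapply(f, `[`, "", 8L)
    endv <- as.integer(getInfo(info, "END"))
    endv[is.na(endv)] <- pos[is.na(endv)]
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = endv),
        strand = strandFromBed(getInfo(info, "STRAND")),
        family = getInfo(info, "FAMILY"), category = "non-reference",
        method = getInfo(info, "METHOD"),
        sample = rep(sample, length(recs)))
}

# ---------------------------------------------------------------------------
# Signal tracks (bedGraph / fixed-step wiggle)
# ---------------------------------------------------------------------------

#' Read a per-base signal track
#'
#' Accepts bedGraph or wiggle (fixed/variable step, auto-detected) and
#' expands it to per-base values. Uncovered positions are `NA`.
#' Overlapping bedGraph intervals with conflicting values are an error;
#' overlaps that agree are merged.
#'
#' @param path Track path.
#' @param seqlengths Optional named vector of chromosome lengths; defaults
#'   to the furthest covered position per chromosome.
#' @return A named [S4Vectors::RleList]-like list of numeric
#'   [S4Vectors::Rle] per chromosome (`NA` where uncovered).
#' @export
readTrack <- function(path, seqlengths = NULL) {
    if (!file.exists(path))
        stopf("file not found: %s", path)
    lines <- readLines(path, n = 50L)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(readLines(path)) || !length(lines))
        return(S4Vectors::SimpleList())
    isWig <- any(grepl("^(fixedStep|variableStep)", lines)) ||
        any(grepl("type=wiggle", lines))
    fmt <- if (isWig) "wig" else "bedGraph"
    gr <- rtracklayer::import(path, format = fmt)
    trackFromGRanges(gr, seqlengths = seqlengths)
}

# Build the per-base NA-padded RleList from a scored GRanges.
trackFromGRanges <- function(gr, seqlengths = NULL) {
    if (!length(gr))
        return(S4Vectors::SimpleList())
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov)) {
        sc <- gr$score
        bad <- sc[S4Vectors::queryHits(ov)] != sc[S4Vectors::subjectHits(ov)]
        if (any(bad))
            stopf("overlapping track intervals with conflicting values near %s:%d",
                  as.character(GenomicRanges::seqnames(gr))[
                      S4Vectors::queryHits(ov)[which(bad)[1L]]],
                  GenomicRanges::start(gr)[
                      S4Vectors::queryHits(ov)[which(bad)[1L]]] - 1L)
        # agreeing overlaps: keep per-score reduction
        pieces <- lapply(split(gr, gr$score), function(g) {
            r <- GenomicRanges::reduce(g)
            r$score <- rep(g$score[1L], length(r))
            r
        })
        gr <- sort(unlist(GenomicRanges::GRangesList(pieces),
                          use.names = FALSE))
    }
    chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
    out <- lapply(chroms, function(ch) {
        g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
        g <- g[order(GenomicRanges::start(g))]
        len <- if (!is.null(seqlengths) && ch %in% names(seqlengths))
            as.integer(seqlengths[[ch]]) else max(GenomicRanges::end(g))
        if (any(GenomicRanges::end(g) > len))
            stopf("track interval beyond length of %s", ch)
        s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
        gap <- s - c(1L, utils::head(e, -1L) + 1L)
        vals <- as.vector(rbind(NA_real_, g$score))
        lens <- as.vector(rbind(gap, e - s + 1L))
        tailGap <- len - e[length(e)]
        if (tailGap > 0L) {
            vals <- c(vals, NA_real_)
            lens <- c(lens, tailGap)
        }
        S4Vectors::Rle(vals[lens > 0L], lens[lens > 0L])
    })
    names(out) <- chroms
    S4Vectors::SimpleList(out)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal values are merged; `NA` runs are omitted (uncovered).
#'
#' @param track Track as returned by [readTrack()] (list of numeric `Rle`
#'   per chromosome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (ch in names(track)) {
        r <- S4Vectors::Rle(as.numeric(track[[ch]]))
        v <- S4Vectors::runValue(r)
        l <- S4Vectors::runLength(r)
        e <- cumsum(l)
        s0 <- e - l
        keep <- !is.na(v)
        if (!any(keep)) next
        writeLines(sprintf("%s\t%d\t%d\t%s", ch, s0[keep], e[keep],
                           format(v[keep], scientific = FALSE, trim = TRUE)),
                   con)
    }
    invisible(path)
}

# ---------------------------------------------------------------------------
# JSON configuration
# ---------------------------------------------------------------------------

configKeyMap <- c(
    replicates = "replicates", tsd_len = "tsdLen",
    strand_policy = "strandPolicy", family_policy = "familyPolicy",
    read_len = "readLen", paired = "paired", insert_mean = "insertMean",
    insert_sd = "insertSd", error_rate = "errorRate",
    coverages = "coverages", simulator = "simulator", seed = "seed",
    windows = "windows")
configPathKeys <- c("genome", "library", "sites", "taxonomy", "out_dir")

#' Load a simulation configuration from JSON
#'
#' Missing keys are filled with defaults (windows 0, 5, 100, 300, 500;
#' random strand; built-in simulator); all invariants are validated and
#' unknown keys are rejected.
#'
#' @param path JSON file with keys among: `replicates`, `tsd_len`,
#'   `strand_policy`, `family_policy`, `read_len`, `paired`,
#'   `insert_mean`, `insert_sd`, `error_rate`, `coverages`, `simulator`,
#'   `seed`, `windows`, plus file paths `genome`, `library`, `sites`,
#'   `taxonomy`, `out_dir`.
#' @return A [SimConfig-class].
#' @export
loadConfig <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.list(obj))
        stopf("config must be a JSON object: %s", path)
    unknown <- setdiff(names(obj), c(names(configKeyMap), configPathKeys))
    if (length(unknown))
        stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    args <- list()
    for (k in intersect(names(obj), names(configKeyMap))) {
        v <- obj[[k]]
        if (k == "family_policy" && is.list(v))
            v <- unlist(v)
        args[[configKeyMap[[k]]]] <- v
    }
    args$paths <- obj[intersect(names(obj), configPathKeys)]
    tryCatch(do.call(simConfig, args), error = function(e)
        stopf("invalid config %s: %s", path, conditionMessage(e)))
}
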