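# Deterministic toy-dataset generator: a small genome, TE library,
# annotations, permissible-site BEDs for the two insertion models, an
# occupancy track, and a taxonomy table -- everything the benchmark and
# annotation layers need, generated in code.

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a deterministic toy dataset
#'
#' Writes, under `outDir`: a 3-chromosome ~100-kb genome
#' (`genome.fasta`), a 3-family TE library with internal coding regions
#' (`te_library.fasta`, `internal_regions.bed`), 20 toy tRNA features
#' (`trna.bed`), permissible-site BEDs for a tRNA-promoter insertion
#' model (`sites_promoter.bed`, strand-aware windows upstream of each
#' tRNA TSS) and a unique-region model (`sites_unique.bed`), a synthetic
#' nucleosome-like occupancy track with sinusoidal peaks upstream of each
#' tRNA (`occupancy.bedGraph`), and a taxonomy table (`taxonomy.tsv`).
#' Byte-identical for identical seeds.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed.
#' @param force Overwrite an existing non-empty directory.
#' @return Named list of the paths written, invisibly.
#' @export
makeFixtures <- function(outDir, seed = 1L, force = FALSE) {
    if (dir.exists(outDir) && length(list.files(outDir)) && !force)
        stopf("directory %s is not empty (use force = TRUE)", outDir)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    withSeed(seed, {
        chromLens <- c(chrI = 40000L, chrII = 35000L, chrIII = 25000L)
        genome <- Biostrings::DNAStringSet(vapply(chromLens, randomDna, ""))
        names(genome) <- names(chromLens)
        writeGenome(genome, p("genome.fasta"))

        lib <- Biostrings::DNAStringSet(c(
            TY1 = randomDna(1200L), TY2 = randomDna(900L),
            TY3 = randomDna(600L)))
        writeGenome(lib, p("te_library.fasta"))
        internal <- data.frame(
            family = c("TY1", "TY2", "TY3"),
            start = c(200L, 150L, 100L), end = c(1000L, 750L, 500L))
        writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", internal$family,
                           internal$start, internal$end,
                           paste0(internal$family, "_internal")),
                   p("internal_regions.bed"))

        copies <- sprintf("%s_%d", rep(c("TY1", "TY2", "TY3"), each = 4L),
                          rep(1:4, 3L))
        writeLines(sprintf("%s\t%s", copies,
                           rep(c("TY1", "TY2", "TY3"), each = 4L)),
                   p("taxonomy.tsv"))

        # 20 tRNA genes on a jittered grid, away from chromosome edges so
        # the +/-2.5 kb windows around each TSS stay on-chromosome.
        nPer <- c(chrI = 8L, chrII = 7L, chrIII = 5L)
        trnaChrom <- rep(names(nPer), nPer)
        trnaStart0 <- unlist(lapply(names(nPer), function(ch) {
            lo <- 4000L
            hi <- chromLens[[ch]] - 4000L
            grid <- seq(lo, hi, length.out = nPer[[ch]])
            as.integer(round(grid + runif(nPer[[ch]], -500, 500)))
        }), use.names = FALSE)
        trnaStrand <- sample(c("+", "-"), length(trnaChrom), replace = TRUE)
        trnaWidth <- 72L
        writeLines(sprintf("%s\t%d\t%d\ttRNA-%d\t0\t%s", trnaChrom,
                           trnaStart0, trnaStart0 + trnaWidth,
                           seq_along(trnaChrom), trnaStrand),
                   p("trna.bed"))

        # Promoter-model sites: 100-900 bp 5' of each tRNA TSS.
        tss0 <- ifelse(trnaStrand == "+", trnaStart0,
                       trnaStart0 + trnaWidth - 1L)
        promStart0 <- ifelse(trnaStrand == "+", tss0 - 900L, tss0 + 101L)
        promEnd0 <- ifelse(trnaStrand == "+", tss0 - 100L, tss0 + 901L)
        writeLines(sprintf("%s\t%d\t%d\tpromoter-%d\t0\t%s", trnaChrom,
                           promStart0, promEnd0, seq_along(trnaChrom),
                           trnaStrand),
                   p("sites_promoter.bed"))

        # Unique-region model: the complement of the tRNA neighbourhoods
        # (1.5 kb margin), away from chromosome ends.
        uniq <- do.call(rbind, lapply(names(chromLens), function(ch) {
            t0 <- trnaStart0[trnaChrom == ch]
            block <- IRanges::reduce(IRanges::IRanges(
                start = pmax(t0 - 1500L, 1L), end = t0 + 1500L))
            allowed <- IRanges::setdiff(
                IRanges::IRanges(2000L, chromLens[[ch]] - 2000L), block)
            allowed <- allowed[IRanges::width(allowed) >= 500L]
            data.frame(chrom = ch, start = IRanges::start(allowed) - 1L,
                       end = IRanges::end(allowed))
        }))
        writeLines(sprintf("%s\t%d\t%d\tunique-%d\t0\t.", uniq$chrom,
                           uniq$start, uniq$end, seq_len(nrow(uniq))),
                   p("sites_unique.bed"))

        # Occupancy: genome-wide sinusoidal nucleosome-like peaks
        # (~165-bp periodicity, one value per 5-bp block).
        occLines <- unlist(lapply(names(chromLens), function(ch) {
            start0 <- seq(0L, chromLens[[ch]] - 5L, by = 5L)
            val <- round(1 + 0.8 * sin(2 * pi * start0 / 165)^2, 4)
            sprintf("%s\t%d\t%d\t%s", ch, start0, start0 + 5L,
                    format(val, scientific = FALSE, trim = TRUE))
        }), use.names = FALSE)
        writeLines(occLines, p("occupancy.bedGraph"))
    })
    paths <- list(genome = p("genome.fasta"),
                  library = p("te_library.fasta"),
                  internal_regions = p("internal_regions.bed"),
                  taxonomy = p("taxonomy.tsv"), trna = p("trna.bed"),
                  sites_promoter = p("sites_promoter.bed"),
                  sites_unique = p("sites_unique.bed"),
                  occupancy = p("occupancy.bedGraph"))
    jsonlite::write_json(c(list(seed = seed), lapply(paths, basename)),
                         p("fixtures.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(paths)
}
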