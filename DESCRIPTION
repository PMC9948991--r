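Package: tebench
Title: Simulation-Based Benchmarking of Transposable Element Insertion
    Detectors
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate short-read detectors of non-reference
    transposable element (TE) insertions with single synthetic insertion
    simulations. Builds synthetic genomes carrying one TE insertion and its
    target-site duplication, simulates paired-end whole-genome sequencing
    reads, scores detector predictions with a within-N breakpoint window
    scheme into recall and precision curves across fold-coverages, estimates
    TE copy number from depth of coverage normalized to non-repetitive
    regions, and profiles insertion positions relative to tRNA transcription
    start sites and nucleosome occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, S4Vectors, IRanges,
    GenomicRanges, GenomeInfoDb, Biostrings, rtracklayer
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Software, Sequencing, Transposon, Coverage
RoxygenNote: 7.3.3
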