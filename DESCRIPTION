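Package: kepmine
Title: Genome Mining of Kex2-Processed Repeat Proteins in Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Kex2-processed repeat proteins (KEPs) in fungal
    proteomes: secretory precursors carrying an endoplasmic-reticulum signal
    peptide and tandem-repeated peptide units separated by dibasic Kex2
    protease sites (KR, KK, RK, RR).  Implements seed-sliding identity
    voting to mark repeated positions, dibasic-site parsing and the KEP
    acceptance filter, reciprocal-similarity typing of KEPs and their
    repeat units with center-star alignment profiles, gene-neighborhood
    co-occurrence statistics for cyclization-factor (DUF3328) genes, and
    pheromone/mating-factor annotation.  Ships a synthetic proteome
    generator with exact ground truth so the whole pipeline is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    mclust,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
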