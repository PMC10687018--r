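Package: cotransmap
Title: Cotranscriptional RNA Structure Probing by Mutational Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for variable-length cotranscriptional
    RNA chemical probing experiments read out by mutational profiling
    (SHAPE-MaP / DMS-MaP). Builds per-intermediate-transcript reference
    targets and an edit-distance-tolerant 3' end index, demultiplexes
    paired-end reads by chemical-probing channel and transcript length,
    applies neighboring-transcript smoothing, aligns reads and counts
    reverse-transcription-encoded mutations under quality filters,
    computes background-subtracted reactivities, and assembles transcript
    length by nucleotide position reactivity matrices with replicate- and
    neighbor-correlation quality control. Includes a library simulator
    with per-read ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    readr,
    ggplot2,
    generics,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    hexbin,
    withr
Config/testthat/edition: 3
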