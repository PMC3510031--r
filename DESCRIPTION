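Package: mirtail
Title: Simulation and Analysis of 3' Terminal Tailing of Mature miRNAs
    in Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and quantifying
    non-templated 3' nucleotide additions (uridylation and adenylation)
    of mature miRNAs from multiplexed small RNA sequencing libraries.
    Includes a seeded simulator of paired wild-type/knockout FASTQ
    libraries with ground truth, barcode demultiplexing and adapter
    trimming, alignment to a mature-miRNA catalog under an
    internal/3'-end mismatch budget, neighborhood-quality-score filtered
    calling of +1-position additions and unambiguous uridylation, and
    paired comparative statistics (reads-per-million quantification,
    read-length ANOVA, geometric-mean fold-change waterfall analysis,
    and chi-squared goodness-of-fit tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
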