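Package: thermedit
Title: Temperature-Resolved Detection and Quantification of A-to-I RNA Hyper-Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clusters of A-to-I RNA editing (hyper-editing) in short
    RNA-seq reads by base-transformed realignment of otherwise unalignable
    reads, quantifies per-site editing levels and the pooled editing index,
    tests for differential editing between conditions (chi-square with
    Benjamini-Hochberg FDR and coverage/effect-size filters), searches the
    flanking sequence of edited regions for inverted repeats able to form the
    double-stranded RNA that ADAR requires, profiles evolutionary conservation
    around edited sites, and bootstraps gene-set editing indices against an
    expression-matched control pool. Ships a synthetic-data generator that
    plants clustered A-to-G edits with condition-dependent rates, an ADAR-like
    sequence context, strand-balanced reads and inverted repeats, so the whole
    pipeline is testable end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    rtracklayer,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
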