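Package: oligoarray
Title: Design and Analysis of Long-Oligonucleotide Two-Color Expression
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for building and analysing custom long-oligonucleotide
    two-color expression microarrays from EST-derived unigene collections.
    Covers identity-threshold pre-clustering of EST sequences, selection of a
    single 60-70 nt probe per unigene under melting-temperature, GC-content,
    secondary-structure and 3'-proximity constraints, cross-hybridization
    screening by overall identity and longest common substring, spot-level
    quality control against negative-control distributions, within-array
    loess normalization of two-color log-ratios, differential expression by
    per-gene linear models and a permutation-based SAM-style statistic with
    false discovery rate estimation, replicate power planning from
    coefficients of variation, relative qPCR quantification with
    reference-gene stability ranking, and downstream tissue-specificity,
    Fisher enrichment and hierarchical clustering analyses. Seeded simulators
    generate every input with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
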