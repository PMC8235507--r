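Package: snapback
Title: Single-Virion Genome-Configuration Analysis for AAV Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates adeno-associated virus (AAV) particle populations as
    high-accuracy single-molecule long reads covering the major molecular
    configuration classes (canonical genomes, 5'/3' snapback genomes,
    incomplete genomes, genome-deletion mutants, foreign DNA), recovers each
    read's configuration by iterative local alignment of unmatched read
    flanks against the reference, and summarizes the population: category
    composition, snapback arm symmetry, ICG/SBG ratio, and a chi-square test
    of breakpoint uniformity.
License: MIT
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
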