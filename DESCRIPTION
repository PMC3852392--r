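Package: sweeplines
Title: Detecting and Dating Selective Sweeps in Divergently Selected Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scan toolkit for detecting and dating selective sweeps in
    long-term divergent selection experiments sampled at several generations.
    Computes sliding-window expected-heterozygosity profiles, calibrates an
    empirical drift null for profile changes, calls and merges significant
    regions, and dates fixation events from the pattern of fixation across
    selected and relaxed sublines. Also provides genome-wide Fisher exact
    tests of allele-frequency divergence with an ordered -log p regression,
    genome-wide heterozygosity-loss summaries, Gabriel-style haplotype block
    calling from unphased genotypes, and an individual-based Wright-Fisher
    forward simulator with truncation selection on a polygenic trait so the
    whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
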