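Package: grasselect
Title: Lineage Substitution Rates and Branch-Site Selection Tests for
    Grass Cold-Response Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for testing whether a
    labelled gene subset (for example low-temperature-induced genes) shows
    elevated substitution rates and stronger positive selection than the
    genome-wide background across grass lineages. Provides a codon sequence
    simulator with branch-site selection classes along a fixed grass species
    tree, coding-sequence hygiene filters and reciprocal-best-hit orthology,
    GTR+Gamma gene-tree estimation with topology and long-branch quality
    control, pairwise dN/dS estimation against outgroups, branch-site
    (Model A) likelihood-ratio tests with multi-start optimisation and
    naive empirical Bayes site identification, and subset-versus-background
    resampling tests, orchestrated as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
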