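Package: zfrscreen
Title: Design and Long-Read Analysis of Zinc-Finger Recombinase Fusion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering and screening zinc-finger (ZF) fusions of
    Cre-type site-specific recombinases. Covers the combinatorial design of
    lox-zif target sites and ZF-recombinase fusion coding sequences with
    paired recombined/unrecombined reference amplicons; classification of
    noisy long reads against the combinatorial reference set with quality and
    coverage filtering to estimate per-combination recombination rates and
    heat maps; profiling of pentapeptide (15-bp in-frame) insertions along a
    recombinase open reading frame via an affine-gap global aligner;
    position-weight-matrix scanning with exact p-values for lox-like sites
    and flank-constrained ZF motif off-target searches; and synthetic-data
    generators (noisy long reads, insertion libraries, planted genomes) with
    ground-truth tables for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    methods,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
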