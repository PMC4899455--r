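Package: rootforage
Title: Split-Pot Root Foraging Analysis with Nonparametric Effect Sizes and
    Phylogenetic Comparative Checks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing split-pot root-foraging experiments in which
    each pot is divided into a nutrient-rich and a nutrient-poor half.
    Computes per-pot root placement precision (log mass ratio of the two
    halves), species-level foraging and plasticity responses as centered
    Mann-Whitney effect sizes with ordinary-bootstrap stability intervals,
    paired Wilcoxon treatment contrasts, scale-aware trait-response
    correlations with pairwise-complete missing-data handling, and
    phylogenetic signal (Pagel's lambda) and phylogenetic generalized least
    squares regressions. Includes a synthetic-data generator (pure-birth
    trees, lambda-structured trait evolution, skew-located pot allocations)
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phytools,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
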