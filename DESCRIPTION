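Package: phylozone
Title: Phylogeny-Based Spatial Conservation Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to rank landscape cells for protected-area expansion so
    that the tree of life is preserved. From binary species range grids and a
    dated phylogeny, the package builds branch-occurrence feature layers,
    ranks cells by an iterative marginal-loss algorithm (core-area zonation
    or additive benefit function) with optional protected-area lock-in, and
    assesses protection of phylogenetic diversity via Faith's PD, gap
    analysis with range-scaled representation targets, branch-coverage
    statistics, human-pressure classes and novel-climate flagging. A seeded
    synthetic-landscape generator (birth-death trees, autocorrelated climate
    surfaces, niches evolving on the tree, clustered protected-area masks)
    makes the whole pipeline testable without external data. Includes a
    stand-in suitability model with true-skill-statistic evaluation,
    max-TSS binarization, median ensembling, buffered convex-hull clipping
    and dispersal-constrained future ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
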