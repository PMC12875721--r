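Package: axenet
Title: Network Component Analysis of Microalgal Axenisation Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-research on axenisation (contaminant removal)
    workflows reported for phototrophic eukaryotic microalgae. A curated
    master table of publication x species purification attempts is turned
    into weighted directed method networks terminating at an incubation
    sink; the package computes edge density and degree statistics under the
    conventions used in the source literature, partitions method networks by
    exact (branch-and-bound) or greedy modularity maximisation, enumerates
    maximal cliques with Bron-Kerbosch pivoting, estimates per-method success
    rates with a minimum-representation filter, scores publication quality
    with a five-question three-rater rubric, and summarises antibiotic
    classes, concentrations and cocktail combinations. A seeded synthetic
    master-table generator with planted method clusters and known success
    probabilities makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
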