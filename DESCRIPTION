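Package: swarmtaxis
Title: Collective Chemotactic Navigation of Bacteria-Inspired Swarms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional agent-based simulator of collective chemotactic
    navigation on complex terrains. Agents perform run-and-tumble motion with a
    tumble-angle variance that shrinks as the measured concentration gain grows,
    interact through zonal repulsion/alignment/attraction rules, and can adapt
    the weight given to neighbours according to their own recent performance.
    The package provides the static Bessel-bowl concentration terrain with
    periodic obstacles, the agent dynamics, zonal interaction rules and weight
    policies, group-performance metrics (median path length, error fraction,
    polar alignment, cluster counts), and ensemble/sweep orchestration with
    fully reproducible seeding. A compiled core keeps large parameter sweeps
    fast; all results are returned as tidy tibbles with ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
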