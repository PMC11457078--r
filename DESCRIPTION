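Package: imdsim
Title: Induced Versus Constitutive Immune Defense in the Drosophila Imd Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of the Drosophila melanogaster Imd
    (immune deficiency) signaling pathway as a system of nine coupled
    ordinary differential equations with three negative-feedback loops
    (PGRP-LB, Pirk, and the repressosome), together with a one-equation
    constitutive-defense model. Provides generators for lattice
    environments of bacterial colonies with controlled density and
    patchiness, deterministic sinusoidal and stochastic random-walk
    encounter models, exponential fitness functions over time-averaged
    pathway activity, stochastic hill-climbing and grid-search
    optimization of defense strategies, and experiment drivers for
    fitness-grid heat maps, the proportion of induced wins (PIW),
    multi-environment fluctuation sampling, and negative-regulator
    perturbation scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
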