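Package: rxnscale
Title: Multiscale Analysis of Reaction-Kinetics Models of Collective Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses plain-text reaction-kinetics rule sets describing systems of
    interacting agents (chemical species, animal groups, opinion states) and
    automatically derives the population-level mathematics at three consistent
    scales: mean-field mass-action ordinary differential equations with phase
    portraits, fixed-point classification and codimension-one bifurcation
    continuation; the chemical master equation with its van Kampen system-size
    expansion, linear-noise moments and stationary fluctuation covariances; and
    exact Gillespie stochastic simulation together with network-embedded
    agent-based simulation on complete, random, scale-free and (static or
    time-varying) geometric interaction topologies. A small exact
    rational-polynomial engine underpins the symbolic derivations. Packaged
    fixture models (a honeybee stop-signal decision model, the Brusselator,
    Lotka-Volterra dynamics, and birth/annihilation toy models) exercise every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
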