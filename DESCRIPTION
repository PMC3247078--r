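Package: switchpool
Title: Stochastic Bistable Switch Dynamics and Follicle Pool Depletion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-scale model linking rare stochastic transitions of a
    two-component bistable genetic switch to decades-long depletion of a
    cell pool, applied to growth initiation of ovarian follicles.
    Provides deterministic analysis of the positive-feedback switch
    (equilibria, stability, trajectories), a continuous-time Markov
    formulation on a truncated state space with an absorbing on-state
    (chemical master equation, sparse generator, dominant eigenvalue and
    switching half-life), exact Gillespie simulation, binomial statistics
    of pool depletion times, a delayed-feedback two-compartment population
    model in which growing follicles suppress initiation, one-at-a-time
    parameter sensitivity scans, and a synthetic-cohort generator for
    inter-individual variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
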