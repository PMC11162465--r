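Package: rbcme
Title: Rao-Blackwellized Solvers for Chemical Master Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Divide-and-conquer solvers for chemical master equations (CMEs) of
    high-dimensional stochastic reaction networks. The package decomposes a
    network into a low-dimensional leader system and conditionally independent
    follower subsystems via automated topological conditions, then combines
    exact stochastic simulation of the leader with filtered finite-state-
    projection solutions of each follower subsystem (Rao-Blackwellization).
    Includes the Gillespie stochastic simulation algorithm, finite state
    projection with sink-mass error bounds, stochastic filtering from noisy
    time-course observations (exact, bootstrap particle filter, and
    Rao-Blackwellized particle filter), cell-specific parameter identification
    on discrete parameter grids, a dual-reporter-free intrinsic/extrinsic
    noise decomposition for single-cell time-course data, and benchmark
    gene-expression fixtures (linear chains, repressilator, toggle switch,
    a three-state yeast transcription model).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
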