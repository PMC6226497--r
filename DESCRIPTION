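Package: tpfret
Title: Photon-by-Photon Maximum-Likelihood Analysis of Single-Molecule
    FRET Binding Transition Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting transition-path times and intermediate
    transfer efficiencies from two-channel single-molecule FRET photon
    trajectories of binding reactions. Implements the continuous-time
    Markov photon likelihood (matrix-exponential propagation with
    per-photon renormalization), two-state versus three-state log-likelihood
    difference surfaces over the intermediate lifetime and transfer
    efficiency, per-transition maximum-likelihood estimates with bootstrap
    errors and deletion controls, FRET calibration (background, crosstalk,
    gamma), blinking detection and transition-window selection,
    Smoluchowski transition-path-time densities on one-dimensional
    free-energy surfaces via spectral expansion, Brownian-dynamics path
    simulation, chi-square and k-sample Anderson-Darling comparison of
    transition-path-time histograms against candidate barrier shapes with
    diffusion-coefficient calibration, Kramers barrier arithmetic, and a
    synthetic photon-trace generator matched to experimental count-rate
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
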