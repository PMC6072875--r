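Package: spinecal
Title: Mechanistic and Input-Output Models of Dendritic Spine Calcium Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates calcium dynamics in a CA1 glutamatergic postsynaptic
    spine with a two-compartment (PSD/spine head) mechanistic model: an
    8-state NMDA receptor kinetic scheme with voltage-dependent magnesium
    block, T-type voltage-dependent calcium channels, PMCA and NCX Hill-type
    extrusion, calmodulin/calbindin/generic calcium-binding-protein buffering,
    and a SERCA/ryanodine-receptor endoplasmic-reticulum store, driven by
    presynaptic glutamate events and backpropagating action potentials.
    Also provides a two-input third-order Volterra series on orthonormal
    Laguerre bases (with cross-kernels) as a reduced-order surrogate of the
    mechanistic model, with pseudoinverse coefficient estimation and
    gradient-descent optimization of the basis decays, plus experiment
    drivers for single-event calibration, pre/post interval sweeps, surrogate
    training/validation and a linear first-order baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
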