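Package: activesheet
Title: Dense Active Matter Models of Collective Motion in Confluent Cell Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for motion patterns in confluent
    epithelial cell monolayers treated as dense active matter. Provides an
    active Brownian soft-disk model and a self-propelled Voronoi (SPV) model
    with overdamped dynamics, normal-mode linear-response analysis of jammed
    packings (Hessian assembly, mode spectra, mode-resolved velocity
    correlations, Fourier-space dynamical matrix and elastic moduli
    extraction), closed-form and numerically integrated continuum-elastic
    predictions for velocity correlation functions, estimators for Fourier-
    and real-space velocity correlations, the self-intermediate scattering
    function and temporal autocorrelations, a fitting pipeline that extracts
    the transverse velocity correlation length from PIV-style gridded
    velocity fields, and a synthetic velocity-field generator for testing
    the full pipeline without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    graphics,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
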