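Package: bzep
Title: Monodomain Simulation of Infarct Border-Zone Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Idealized two-dimensional simulations of electrical activation and
    repolarization around a healed myocardial infarct. Provides the ten
    Tusscher-Panfilov (2006) human ventricular ionic model with scalable slow
    delayed-rectifier conductance, a synthetic scar/border-zone sheet geometry
    generator with anisotropic fiber fields, finite-element monodomain
    reaction-diffusion integration, automatic conductivity calibration to
    target conduction velocities, and extraction of activation-time,
    repolarization-time and repolarization-gradient maps for a panel of
    computational border-zone representations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
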