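Package: speccal
Title: Illumination Calibration and White-Reference Prediction for
    Surgical Hyperspectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for illumination calibration of hyperspectral image
    cubes in dynamically lit environments such as operating rooms.
    Provides cube arithmetic (white-reference calibration and synthetic
    relighting), a physics-inspired simulator of plausible white-reference
    cubes built on a Planck-like parametric light spectrum with
    least-squares fitting, interval sampling and spatialization, K-means
    based illumination libraries with inter-cluster interpolation, a 3D
    convolutional encoder-decoder that predicts the white-reference cube
    corresponding to an uncalibrated input (trained with relighting
    augmentation, Adam and an exponentially decaying learning rate), a
    spatially uniform ablation variant, classical illuminant-estimation
    baselines (Gray world, Max-RGB, first-order Gray edge), and an
    evaluation suite based on spectral cosine similarity with bootstrap
    intervals. Includes a fully seeded synthetic-data generator emulating
    halogen- and LED-type camera spectra, stray-light scenarios,
    tissue-like scenes and colorchecker boards, so the whole pipeline is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    rhdf5,
    MASS,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
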