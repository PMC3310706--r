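Package: hemowave
Title: Spatiotemporal Hemodynamic Response Modelling and BOLD Wave Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linearized poroelastic model of cortical hemodynamics predicting
    a damped-traveling-wave spatiotemporal BOLD response (stHRF), together
    with the empirical pipeline for detecting and quantifying hemodynamic
    waves on cortical flat maps. Includes a spectral (Fourier transfer
    function) solver with a finite-difference time-domain oracle, a
    synthetic flat-map fMRI data generator emulating a V1 line-stimulus
    block-design experiment, Hilbert-transform phase-front tracking, and
    regression estimators for wave speed, spatial and temporal damping, and
    response width, validated by parameter recovery on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
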