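Package: ptxspsp
Title: Parallel-Transmission Spatial-Spectral RF Pulse Design for
    Slab-Selective Water Excitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of parallel-transmission (pTx)
    spatial-spectral radiofrequency pulses for slab-selective, uniform,
    water-only excitation at ultra-high field. Implements a comprehensive
    four-dimensional (1D spectral x 3D spatial) regularized
    magnitude-least-squares formulation solved by variable exchange, with
    bipolar trapezoidal slab-selective gradients and a SPINS-like
    in-plane excitation k-space trajectory. Includes a synthetic
    multi-channel head-coil calibration generator, small-tip-angle
    spatial-domain system matrices, a hard-pulse Bloch simulator for
    flip-angle maps, slab profiles, spectral response patterns and
    gradient-delay sensitivity, traditional multi-spoke and binomial
    composite-pulse baselines, and excitation-quality metrics (RMSE,
    coefficient of variation) with a multi-subject robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
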