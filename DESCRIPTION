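Package: EndoFPP
Title: Single-Shot Fringe Projection Profilometry for Endoscopic Depth
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-shot fringe projection profilometry (FPP)
    aimed at endoscopic tissue surface reconstruction. Provides a
    projector pattern generator (sinusoidal and binary fringes with
    phase-shift sequences), an analytic structured-light scene simulator
    with Poisson shot noise that renders fringe-illuminated images of a
    diamond-shaped tissue phantom together with ground-truth depth, the
    conventional multi-frequency phase-shifting pipeline (four-step phase
    retrieval, temporal phase unwrapping, rational phase-to-depth
    calibration, variance-based segmentation), a two-path convolutional
    depth predictor (MaskNet/DepthNet, a modified five-level U-Net with
    multi-level output heads trained with L1+SSIM and Dice losses), depth
    and segmentation evaluation metrics, a frequency-sweep and ablation
    harness, and point-cloud export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    tiff,
    yaml,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
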