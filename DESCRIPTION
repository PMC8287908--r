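Package: spotnet
Title: Threshold-Independent Detection and Sub-Pixel Localization of
    Diffraction-Limited Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and localizes diffraction-limited fluorescent spots in 2D
    microscopy images without manual intensity thresholds. A fully convolutional
    network (U-Net encoder-decoder with squeeze-and-excitation blocks and a
    second grid-resolution encoder) regresses, for every grid-cell of the image,
    a spot probability and a sub-pixel within-cell offset, and is trained with a
    dice classification loss plus a doubly weighted localization loss. The
    package ships the complete toolchain: a synthetic spot-field simulator with
    exact continuous ground truth, dataset assembly from TIFF/PNG images and
    coordinate CSVs (including TrackMate exports) into a partitioned archive,
    model training with AMSGrad, sub-pixel prediction with optional Gaussian
    refinement, a Laplacian-of-Gaussian baseline detector with automated
    quantile threshold selection, and evaluation via Hungarian-matched F1
    integral score, F1 at 3 px, and localization RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    png,
    yaml,
    minpack.lm,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
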