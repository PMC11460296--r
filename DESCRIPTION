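Package: pzseg
Title: Prostate Gland and Peripheral Zone Segmentation with a Searched 2D-3D CNN Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-prostate and peripheral-zone segmentation of
    T2-weighted MR volumes with an ensemble of dual-decoder residual
    encoder-decoder convolutional networks. Provides a synthetic prostate
    phantom generator with ground-truth masks, planar contour (RT-STRUCT
    style) to voxel-mask conversion, geometric and intensity preprocessing,
    a hyperparameter-defined 2D/3D network family with native training code,
    Bayesian hyperparameter optimization with a Gaussian-process surrogate,
    five-fold 2D-3D ensemble training with majority voting, and the full
    evaluation stack: Dice score, Hausdorff distance, cohort intensity
    discrepancy metrics, and volume-stratified statistical reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
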