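Package: cardiomark
Title: Heatmap-Based Anatomical Landmark Detection for Cardiac MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects anatomical landmarks (valve-plane and apical points on
    long-axis views; right-ventricular insertion points and the left-
    ventricular centre on short-axis views) in 2D cardiac MR images by
    encoding each landmark as a Gaussian spatial-probability heatmap and
    training a U-Net to predict the per-pixel class distribution with a
    combined Kullback-Leibler + soft-Dice loss.  Includes preprocessing to a
    fixed millimetre grid with surface-coil bias-field correction, decoding
    with absent-landmark handling, derived clinical measurements (LV length,
    anterior RV-insertion angle, longitudinal-shortening curves), transfer-
    learning fine-tuning, and a synthetic cardiac phantom generator so the
    whole pipeline can be trained and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    RNifti
Config/testthat/edition: 3
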