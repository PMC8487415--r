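Package: dotapet
Title: Automated Hepatic Lesion Detection for 68Ga-DOTATATE PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for automated detection of somatostatin-receptor
    PET (68Ga-DOTATATE) hepatic lesions: synthetic liver-phantom generation,
    semi-automated gold-standard annotation (background-sphere statistics,
    modified PERCIST thresholding, gradient-edge boundary refinement), a 2D
    residual U-Net with contextual aggregation layers trained on a 6:1
    combination of binary cross-entropy and Dice losses, pixel-area noise
    filtering of predictions, and lesion-level evaluation (PPV, sensitivity,
    F1, precision-recall AUC) with replicate aggregation. Includes a compact
    CPU convolutional-network engine with exact gradients and a PNG-based
    dataset layout with stratified splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
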