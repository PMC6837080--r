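Package: semgraphics
Title: Semantic-Graphics Learning for Crop-Row and Weed Detection in Paddy Fields
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains convolutional encoder-decoder networks on semantic
    graphics: sparse vector annotations (polylines for crop rows,
    depth-scaled discs for plant bases) rasterized into label masks.
    Implements the extended-skip architecture (large separable kernels at
    the encoder tail, learned multi-scale skip connections contributing a
    constant 12 extra channels), class-weighted pixel-wise cross-entropy
    training with Adam and stepwise exponential learning-rate decay, a
    RANSAC-like dominant-line extractor for navigation, evaluation metrics
    (per-class IoU and mIoU, distance-thresholded keypoint
    precision/recall/F1, mean pixel deviation of extracted lines), and a
    seeded synthetic paddy-scene generator that produces images with exact
    ground-truth graphics so the whole pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: zlib
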