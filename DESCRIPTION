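Package: dropseg
Title: Label-Free Lipid Droplet Segmentation in Quantitative-Phase Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of cytosolic lipid droplets in label-free
    quantitative-phase images (QPI) of single cells. Implements per-pixel
    classification on an 80-filter image feature bank with five classical
    backends (random forest, gradient boosting, support vector machine,
    multilayer perceptron, linear discriminant analysis), a U-Net style
    fully convolutional segmenter with its own CPU training engine, the
    six-score evaluation suite (accuracy, balanced accuracy, precision,
    recall, Sorensen-Dice, Jaccard) with ROC/AUC, a k-fold cross-validation
    and training-set-size experiment harness, and a synthetic QPI scene
    generator that provides exact ground-truth masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    ranger,
    xgboost,
    e1071,
    MASS,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
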