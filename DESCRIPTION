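Package: haarnet
Title: Spectral-Spatial Wavelet-Fusion Convolutional Networks for Histology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multilevel 2D Haar wavelet decomposition fused by concatenation
    into a convolutional classification network for histopathology patch
    classification. Provides the parameter-free Haar filter bank and wavelet
    pyramid (with raw, orthonormal and average-pooling-equivalent
    normalizations), a declarative layer-graph builder with closed-form shape
    propagation and trainable/non-trainable parameter auditing, a CPU
    reference training backend, deterministic patch extraction with 50%
    overlap and 8-fold dihedral augmentation, classification metrics
    (confusion counts, sensitivity, specificity, ROC/AUC with one-vs-rest
    multi-class reduction), and a seeded generator of class-separable
    synthetic histology-like images so the full pipeline is testable without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
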