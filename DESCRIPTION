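Package: rpcseg
Title: Residual Pancreatic Cancer Segmentation with Multi-Scanner
    Cross-Validation and Meta-Analytic Pooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pixel-level segmentation of residual
    pancreatic cancer (RPC) in hematoxylin-and-eosin regions of interest:
    annotation taxonomy and class merging, polygon rasterization, balanced
    patch sampling, stain-deconvolution color normalization and training-time
    augmentation, a compact convolutional encoder-decoder trained with
    per-channel binary cross-entropy, weighted sliding-window stitched
    inference, per-class F1 evaluation, leave-one-scanner-out
    internal-external cross-validation, and random-effects meta-analytic
    pooling of per-scanner performance (REML between-study variance with a
    Hartung-Knapp-Sidik-Jonkman interval and a Jackson-type variance floor).
    Includes a seeded synthetic multi-scanner H&E-like cohort generator so
    every stage is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
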