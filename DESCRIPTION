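Package: garnet
Title: Guided Attention Residual Networks for Polyp Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder convolutional network for binary polyp
    segmentation from colonoscopy frames, built around modified residual
    blocks with learned skip projections, a per-channel guided attention
    module that gates low-level skip features with sigmoid attention map
    sets, and guided attention learning: deep supervision that trains a
    consolidated single-channel attention map at every decoder stage
    against the resized ground-truth mask. Includes the multi-task loss
    (soft dice plus per-stage binary cross-entropy), segmentation metrics
    (Dice, mean IoU, pixel accuracy), a paired image/mask augmentation and
    preprocessing pipeline, a seeded generator of synthetic polyp-like
    image/mask pairs so the whole stack runs without external data, a
    training loop (Adam, learning-rate plateau, best-validation
    checkpointing), and a command-line interface. The convolution,
    batch-normalization and bilinear-upsampling forward/backward kernels
    are implemented in compiled code; no external deep-learning runtime
    is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tibble,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    tiff
Config/testthat/edition: 3
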