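Package: gtvseg
Title: 2.5D Residual Squeeze-and-Excitation U-Net with a Transformer
    Bottleneck for Volumetric CT Target Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic segmentation of a gross target volume (GTV)
    in thick-slice radiotherapy CT. Implements a five-stage encoder-decoder
    whose shallow stages convolve only in-plane (2.5D), residual
    squeeze-and-excitation feature blocks, and a bottleneck that serializes
    the deepest feature map into tokens and applies multi-head self-attention
    before a residual merge. Ships the full training protocol (summed Dice
    and cross-entropy loss, Adam with polynomial learning-rate decay,
    random-crop training and GTV-centered validation with best-checkpoint
    selection), Dice and 95th-percentile Hausdorff evaluation with
    anisotropic spacing, and a seeded anisotropic CT phantom generator so
    that every component is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
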