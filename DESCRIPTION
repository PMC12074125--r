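Package: axunet
Title: Cross-Axis Attention U-Net for Biomedical Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder (U-Net style) binary segmentation network with
    multi-head multi-scale cross-axis attention blocks and a gated efficient
    feature-fusion module replacing plain skip-connection concatenation.
    Includes a pure-R/C++ training stack (manual backpropagation, Adam),
    confusion-matrix segmentation metrics (mIoU, accuracy, recall), seeded
    generators for nucleus-like and vessel-like synthetic microscopy images
    with exact ground-truth masks, dataset PNG input/output, augmentation, an
    ablation runner, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
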