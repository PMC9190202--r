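Package: her2quant
Title: Quantitative HER2 Scoring of Gastric-Cancer Immunohistochemistry
    Slides with a Re-Parameterizable Tile Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic HER2 immunohistochemistry scoring of
    gastric-cancer whole-slide images. A six-class tile classifier
    (HER2 0/1+/2+/3+, normal tissue, artifact) is built from multi-branch
    convolutional blocks (parallel 3x3, 1x1 and identity branches, each
    with batch normalization) plus optional gated-channel-transformation
    or squeeze-and-excitation channel attention. After training, the
    multi-branch blocks are fused by exact structural re-parameterization
    into single 3x3 convolutions for fast deployment. Slide-level HER2
    scores (0/1+/2+/3+ and negative/equivocal/positive) are predicted
    from the tile-class proportion vector by a polynomial-kernel support
    vector machine or a small multilayer perceptron. A synthetic
    stained-tile generator makes every stage trainable and testable
    without access to clinical slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    png,
    yaml,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
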