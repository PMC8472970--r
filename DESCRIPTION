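Package: gsaunet
Title: Gated Skip-Connection Segmentation Networks with Adaptive Upsampling for Retinal Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements GSAU-Net, an encoder-decoder (U-Net style) convolutional
    network for retinal vessel segmentation with gated skip-connections and
    adaptive (sub-pixel, periodic-rearrangement) upsampling, together with the
    patch-based training protocol used for fundus photographs, ablation variants
    (plain versus gated skips; adaptive versus bilinear versus transposed-convolution
    upsampling), field-of-view restricted evaluation metrics with ROC/PR curves,
    DRIVE-style dataset input/output, and a procedural generator of fundus-like
    vessel phantoms for desk-scale experiments. The convolutional engine (forward,
    backpropagation, Adam) is implemented natively via 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
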