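Package: dropclass
Title: Label-Free Classification of Microfluidic Droplet Images by Cell Count
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies brightfield images of water-in-oil microfluidic
    droplets as empty, single-cell or multiple-cell, in the presence of a
    vertical column of paramagnetic nanobeads (the "beadline") that occludes
    or mimics cells. Implements a beadline-suppressing preprocessing pipeline
    (horizontal-edge Prewitt convolution, bisigmoidal contrast filter,
    resizing, affine intensity normalization and circular masking), a
    residual-network classifier trained by mini-batch stochastic gradient
    descent, three conventional cell-counting baselines (circular Hough
    transform, maximally stable extremal regions, and a morphological
    segmentation sequence), a synthetic droplet-image generator for
    benchmarking, and an evaluation harness reporting per-class accuracy,
    confusion matrices, confidence-threshold retention curves and Welch
    t-test comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
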