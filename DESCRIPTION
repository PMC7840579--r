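Package: hopnet
Title: Multi-Hop Connectivity Propagation Networks for Individual
    Activation Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts a target brain region's functional activation from an
    individual's functional connectivity matrix alone, using a multi-layer
    graph propagation network whose trainable coefficients are imposed
    element-wise on the connectivity matrix, so that the k-th layer carries
    k-hop connectivity information. Includes Gaussian-Gamma mixture
    thresholding of regional activations for task-network selection,
    construction of functional connectivity matrices from region-by-time
    series, normalized-squared-error and correlation metrics with a
    repeated train/test-split protocol, a retrained permutation null, and a
    synthetic cohort generator so the whole pipeline runs without external
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
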