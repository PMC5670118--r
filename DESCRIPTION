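Package: texsparse
Title: Naturalistic Texture Preference and Sparse Firing in Hierarchical
    Visual Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why higher layers of hierarchical visual
    models respond more to images with naturalistic higher-order statistics
    than to spectrally matched (phase-randomized) noise. Implements
    phase-randomized stimulus synthesis and a structured-texture generator,
    grouped higher-order texture statistics with groupwise PCA and
    relative-importance (averaging-over-orderings) regression, a desk-scale
    hierarchical nonnegative sparse-coding network (SHMAX) with max pooling
    and receptive-field geometry calculators, modulation-index and
    sparseness metrics, a ranking distance between orderings with its
    permutation test, random-sampling t-tests, per-unit randomization
    tests, and a synthetic response generator with known ground truth for
    estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    png,
    rlang,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
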