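Package: adafnn
Title: Adaptive Functional Neural Networks for Multivariate Functional
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of multivariate functional data (synchronized
    multi-channel time series such as facial-landmark trajectories and
    physiological recordings) with adaptive basis layers: each channel
    receives a bank of trainable micro-networks whose outputs act as basis
    functions, trial curves are projected onto them by trapezoidal inner
    products, and the fused coefficient vector feeds a small residual
    multilayer perceptron.  Includes sparsity and orthogonality penalties
    on the learned bases, weighted cross-entropy training with early
    stopping, two-stage hyper-parameter tuning, a distance-correlation
    guided forward-backward functional variable selector, a repeated
    stratified-split evaluation harness with normality-gated paired
    comparisons, raw-signal preprocessing utilities, and a synthetic
    multivariate functional data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
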