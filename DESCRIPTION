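Package: lungsop
Title: Second-Order Pooling Networks with Squeeze-Excitation Attention and
    Dynamic Feature Gating for Lung CT Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Building blocks and a full training/evaluation pipeline for a
    covariance (second-order) pooling convolutional classifier aimed at
    three-class lung CT slice classification (benign, malignant, normal).
    Provides trace-normalized covariance pooling with the Newton-Schulz
    matrix square-root iteration and an eigendecomposition oracle,
    squeeze-and-excitation channel attention, an adaptive gate that blends
    the second-order and channel-attention branches with a balance
    regularizer, a ResNet-style bottleneck backbone assembled into the full
    classifier, a seeded three-class CT phantom generator, class-folder
    image ingestion with stratified splitting, augmentation and class
    balancing, and an evaluation battery (confusion matrix, one-vs-rest
    metrics, ROC/AUC, bootstrap confidence intervals, paired t-tests).
    All neural layers are implemented in base R over BLAS matrix products
    with hand-derived backpropagation, so the whole pipeline runs on CPU
    with no external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
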