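Package: clumm
Title: Contrastive Learning for Unobtrusive Motion Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Label-efficient human motion recognition from camera-based pose
    landmarks. Quantizes ten body-joint landmarks per video frame into a
    30-element feature vector, learns frame representations with a SimCLR-style
    contrastive objective (additive jitter and multiplicative scaling
    augmentations, a single-channel residual or multilayer-perceptron encoder,
    and the normalized temperature-scaled cross-entropy loss), classifies
    motion types with a frozen-encoder multinomial logistic regression probe
    under stratified cross-validation, and audits training data for outlier
    motions via K-means nearest-centroid distance thresholds. Includes a
    synthetic pose-sequence generator for the idle/lift/bend motion classes
    used throughout the examples and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
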