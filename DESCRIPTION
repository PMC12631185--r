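Package: leafstack
Title: Hybrid Handcrafted/Deep Feature Stacking for Leaf Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline for classifying plant leaf images into disease
    categories from a hybrid feature representation. Handcrafted descriptors
    (HSV/LAB color histograms, dominant colors by k-means, local binary
    patterns, gray-level co-occurrence statistics, shape descriptors) are fused
    with convolutional features reduced by global average pooling, compressed
    by principal component analysis, and classified by a two-stage stack: a
    classical base learner whose class probabilities feed a dense neural
    network head. Includes local surrogate (LIME-style) explanations, a full
    evaluation suite (classification report, confusion matrix, one-vs-rest
    ROC/AUC), and a seeded synthetic leaf-image generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    randomForest,
    xgboost,
    caret
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
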