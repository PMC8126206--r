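Package: fallphase
Title: Multiphase Fall Identification from a Single Waist-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting a recorded fall event into its constituent
    phases (initial-static, pre-fall, free-fall, impact, resting, recovery,
    ending-static) from tri-axial accelerometer and gyroscope streams sampled
    at a fixed rate. Implements sliding-window statistical feature extraction,
    five machine-learning phase classifiers (linear one-vs-one SVM, k-nearest
    neighbour, Gaussian naive Bayes, CART, and multiclass AdaBoost over
    decision stumps), a rule-based fragment-modification pass that repairs
    short misclassified segment runs, reconstruction of per-sample phase
    timelines, and sample-based evaluation (sensitivity, precision, Jaccard
    coefficient, accuracy) under leave-one-subject-out cross-validation.
    Includes a seeded simulator that generates labelled fall trials following
    a standard laboratory fall protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    optparse,
    Rcpp,
    rpart,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
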