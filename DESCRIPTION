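Package: gefc
Title: Grammatical-Evolution Feature Construction for Wearable-Sensor
    Motor-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for objective ON/OFF-medication motor-state
    classification in Parkinson's disease from tri-axial wearable
    sensor recordings (accelerometer, gyroscope, magnetometer).
    Implements windowed multi-domain feature extraction (statistical,
    energy, spectral, and nonlinear descriptors including Higuchi
    fractal dimension, sample entropy and a Rosenstein-style Lyapunov
    exponent), a tripartite composite feature-ranking scheme combining
    paired t-tests, random-forest Gini importance and PCA loadings,
    grammatical evolution of artificial features via codon-to-rule BNF
    mapping, a genetic algorithm that minimises RBF-network training
    error of the constructed features, cross-validated evaluation
    against RBF and neural-network baselines, and a synthetic
    glove-IMU cohort simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
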