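Package: hrvogtt
Title: Multilead ECG Heart-Rate-Variability Phenotyping During an Oral Glucose Tolerance Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying cardiometabolic autonomic
    phenotypes (metabolic syndrome, healthy controls, endurance athletes)
    from multilead electrocardiograms recorded across the stages of an oral
    glucose tolerance test. Provides multilead Pan-Tompkins R-peak detection
    with median-timing fusion across channels, RR-series artifact handling,
    multidomain heart-rate-variability descriptors (time, frequency via
    Welch estimation, and nonlinear: Poincare, sample and approximate
    entropy, detrended fluctuation analysis), nonparametric group statistics
    (Kruskal-Wallis with Dunn-Bonferroni post hoc), three multimodal
    neural classifiers (1D-CNN and LSTM sequence encoders fused with an HRV
    multilayer perceptron, softmax or linear one-vs-rest SVM heads) under
    strict subject-wise partitioning, multiclass evaluation metrics, and a
    synthetic cohort generator with ground-truth beat annotations so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
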