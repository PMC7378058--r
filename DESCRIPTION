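Package: DeepRadSurv
Title: Deep Learning-Based Radiomics for Time-to-Event Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting time-to-event clinical outcomes (overall
    survival, recurrence-free survival, distant and local control) from paired
    CT/PET tumor image patches and clinical covariates. Implements two small
    convolutional risk networks trained by maximizing the Cox partial
    likelihood (with optional convolutional auto-encoder pre-training), a
    hand-crafted radiomics arm (shape, intensity and gray-level co-occurrence
    texture features reduced by principal component analysis), stepwise Cox
    proportional-hazards modelling with likelihood-ratio selection, a random
    survival forest with logrank splitting and Nelson-Aalen node hazards, and
    Kaplan-Meier / maximally selected logrank cut-off analyses. A seeded
    synthetic-cohort generator emulates the statistical structure of paired
    PET/CT survival data so that the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    jsonlite,
    Rcpp,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ranger,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
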