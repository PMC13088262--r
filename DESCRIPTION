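Package: ctloop
Title: Closed-Loop Surrogate-Guided Optimization of Nucleic Acid
    Extraction Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and orchestration of closed-loop, batch
    design-of-experiments campaigns for magnetic-nanoparticle based viral
    nucleic-acid extraction formulations, benchmarked by qPCR cycle
    threshold (Ct) values. Provides a mixed categorical/continuous
    condition-space encoding with a JSON scheme format, a calibrated
    synthetic Ct response surface with replicate-noise regimes and a
    template-concentration model, industrial-style and literature-style
    initial-dataset generators, cross-validated surrogate model selection
    with permutation-based per-category weighting factors, genetic
    algorithm batch proposal with a rule-based advisor, campaign
    persistence and resumption, and analysis utilities: replicate
    consistency scoring, PCA compactness comparison, campaign comparison
    and weighting-profile reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    glmnet,
    jsonlite,
    kernlab,
    nnet,
    optparse,
    ranger,
    rpart,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
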