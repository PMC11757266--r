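Package: intracirc
Title: Quantified Intraoperative Circulation Features and Prolonged
    Length-of-Stay Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intraoperative circulation from 5-minute vital-sign
    series (systolic/diastolic blood pressure, heart rate, pulse) and predicts
    prolonged postoperative length of stay (PLOS). Implements manual
    circulation assessment metrics (time-weighted hypotension and
    hypertension beyond 30 percent of baseline mean arterial pressure,
    average real variability and its squared generalization), a library of
    machine-learned time-series features (Fourier coefficients, Ricker
    wavelet transform, Lempel-Ziv complexity, approximate entropy,
    permutation entropy, aggregated linear trends, duplicate-value
    fractions), dual-test false-discovery-rate feature selection,
    random-forest and gradient-boosted-tree classifiers with exact tree-SHAP
    attributions, DeLong confidence intervals for the AUROC, and a streaming
    re-scoring engine that recomputes the prediction score on every growing
    5-minute prefix of a surgery. A seeded synthetic-cohort generator with
    known ground truth supports validation when clinical data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pROC,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
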