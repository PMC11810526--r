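Package: mirmibc
Title: Predicting Muscle Invasion of Bladder Cancer from a Small miRNA
    qRT-PCR Panel with Conformal Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis workflow for classifying muscle-invasive
    (MIBC) versus non-muscle-invasive (pTa low-grade) bladder cancer from a
    four-miRNA qRT-PCR panel: triplicate Ct aggregation and expression
    filtering, reference-assay selection and comparative-Ct normalization,
    nonparametric biomarker statistics (Mann-Whitney, Kruskal-Wallis, ROC),
    exhaustive feature-subset model selection across five classifier
    families with cross-cohort validation, adaptive-prediction-sets
    conformal prediction with a user-set coverage guarantee, application of
    the frozen classifier to the intermediate pT1 high-grade group, and
    IHC-marker-based luminal/basal molecular subtyping. Includes a seeded
    synthetic-cohort generator emulating the study design so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    jsonlite,
    kernlab,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
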