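Package: bqsofa
Title: Development and Validation Toolkit for Paediatric Bedside Severity
    Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A declarative engine for rapid bedside paediatric severity
    scores built from binary clinical signs (LqSOFA, BqSOFA and related
    scores), together with the machinery used to develop and validate
    them: age-banded vital-sign cutoff tables, cohort-derived percentile
    cutoffs, an explicit missing-data policy (assume-normal scoring with
    exclusion of records missing two or more components), prognostic
    evaluation (empirical AUC with DeLong confidence intervals,
    sensitivity/specificity/PPV/NPV with exact confidence intervals,
    calibration by score level, binary net reclassification index),
    univariate predictor screening, a stepwise score-amendment engine,
    and a synthetic-cohort simulator with analytic ground truth so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
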