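Package: muralrisk
Title: Mural-Based Lesion Risk Scoring and Diagnostic Strategy
    Cost-Effectiveness for Small Bowel Bleeding
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging patients with potential small bowel
    bleeding. Implements the MURAL logistic risk score for bleeding from
    mural-based lesions (small-bowel tumors) from age, atherosclerosis,
    chronic kidney disease, antiplatelet use and serum albumin; the full
    model-derivation pipeline (cohort splitting, univariate screening,
    maximum-likelihood logistic fitting, Youden-index cutoff selection and
    hold-out validation); a deterministic expected-value decision model
    comparing six diagnostic strategies built from video capsule endoscopy
    (VCE), computed tomography enterography (CTE) and model-based triage,
    with one-way sensitivity analysis over published parameter ranges; and
    synthetic patient-cohort generators that double as Monte-Carlo oracles
    for the analytic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
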