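Package: heartage
Title: Predicted Heart Age and Treatment Eligibility from STEPS-Style Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the sex-specific Framingham 10-year general cardiovascular
    disease risk (office-based and lipid-based variants), inverts it to a
    predicted heart age against an ideal risk-factor reference profile with
    "<30"/">80" censoring, and classifies the gap between predicted heart age
    and chronological age. Includes STEPS-style survey cleaning with
    plausibility filtering, WHO HEARTS antihypertensive and lipid-lowering
    treatment-eligibility rules, design-aware (stratified cluster) prevalence
    estimation, mixed-effects logistic models for correlates of excess heart
    age, and a synthetic multi-country survey generator with known ground
    truth so the whole pipeline is testable without restricted microdata.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    lme4,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
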