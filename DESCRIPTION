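Package: petriage
Title: Pulmonary Embolism Rule-Out Algorithms and Diagnostic Accuracy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the five authoritative pulmonary-embolism (PE)
    likelihood-prediction algorithms -- Standard, Age-adjusted D-dimer,
    YEARS, PERC and PEGeD -- as deterministic rule engines over patient
    records, together with the diagnostic-test-accuracy machinery needed to
    compare them on a cohort: Wells score and clinical pretest probability
    (C-PTP) classification, 2x2 confusion matrices against a confirmed-PE
    reference standard, an eight-metric accuracy panel (sensitivity,
    specificity, PPV, NPV, likelihood ratios, Youden index, diagnostic
    accuracy), pairwise imaging-burden and missed-diagnosis comparisons,
    and between-group cohort characteristic tables (t-test / chi-square).
    A calibrated synthetic cohort generator emulates the demographic and
    clinical structure of an AECOPD population with high PE prevalence so
    that every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
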