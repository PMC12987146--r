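Package: oncotol
Title: Treatment-Tolerance Monitoring Analytics for Oncology Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating remote-monitoring alerting
    pipelines for oncology patients on immunotherapy plus chemotherapy.
    Provides a rule-based parametric simulator of weekly adverse-effect
    panels with patient-level susceptibility and trigger-target symptom
    correlations, a configurable rule-based proxy for the "low treatment
    tolerance" label, generators of wearable-style physiological signal
    fixtures (sleep, blood pressure, weight, skin temperature, surveys),
    rule-based clinical detectors that turn those signals into weekly
    binary symptom flags, feature engineering for the 30-column model
    input, patient-wise data splitting with min-max scaling and four
    classifier families, decision-threshold sweeps, and symptom
    co-occurrence statistics (prevalence, phi coefficient, chi-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    xgboost,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
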