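Package: riskreclass
Title: Risk-Model Augmentation Analysis for Incident Myocardial Infarction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-stratified Cox proportional-hazards modelling of incident
    myocardial infarction with Framingham-style covariate coding, Breslow
    baseline-hazard estimation and 10-year predicted risk, and evaluation of
    added risk markers (an additively coded SNP, a dominantly coded SNP, and a
    continuous inflammatory biomarker) by change in ROC AUC (DeLong test) and
    categorical Net Reclassification Improvement. Includes a calibrated
    synthetic-cohort generator emulating an elderly prospective cohort so the
    whole pipeline is testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
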