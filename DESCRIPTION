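Package: csiscore
Title: CSI-Score Grading of Mesenteric Artery Stenosis from CT Angiography Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation, computation and internal validation of the CSI-score, an
    integer weighted-sum severity score for stenosis of the three visceral arteries
    (celiac, superior and inferior mesenteric) measured on CT angiography. Converts
    per-vessel lesion measurements (reach category, residual and reference luminal
    diameters or percent stenosis, occlusion flags) into extent and grade scales,
    combines them into the score, derives score weights by grid search maximising a
    tie-aware rank-based AUC, selects the Youden-optimal cut-off, computes
    Brunner-Munzel confidence intervals for the AUC, bootstraps discriminative
    performance, quantifies inter-rater agreement (percent agreement and Cohen's
    kappa), and simulates synthetic patient cohorts for testing the pipeline
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
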