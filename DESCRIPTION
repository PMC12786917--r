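Package: endoscreen
Title: Questionnaire-Based Non-Invasive Prediction of Endometriosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pain-questionnaire data in suspected
    endometriosis. Implements a codebook-driven patient-record model with
    delimited-file input/output and validation, composite symptom scores
    (sum of pain intensity scales, PainDETECT neuropathic-pain final score
    and band, and a 34-item significant-parameter count), a serialisable
    binary decision-tree classifier with a shipped default rule,
    diagnostic-accuracy statistics (Fisher's exact test, Mann-Whitney,
    sensitivity/specificity/predictive-value panels with confidence
    intervals, ROC cut-off selection), and a calibrated synthetic cohort
    generator based on a Gaussian copula so that every pipeline stage can
    be exercised without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
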