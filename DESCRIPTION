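Package: seizeval
Title: Evaluation of Wearable Convulsive-Seizure Detection Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating wrist-worn multimodal (accelerometer plus
    electrodermal activity) convulsive-seizure detection devices against a
    video-EEG reference standard. Implements majority-rule adjudication of
    independent reviewer annotations, alarm-to-seizure matching with latency
    scoring, false-alarm rates per 24 hours worn, cluster-corrected Wilson
    sensitivity intervals with ANOVA intraclass-correlation and design-effect
    machinery, Laplace rule-of-succession precision, patient-level bootstrap
    confidence intervals for event rates, exposure-adjusted rate-ratio tests,
    clustered sample-size planning, ROC and precision-recall curves built on
    pseudo-negative events, an actigraphy rest-detection algorithm, a
    transparent surrogate detector, and synthetic cohort and signal
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
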