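Package: hemotrend
Title: Method-Comparison and Trending Analysis for Cardiac Output Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing a test cardiac-output (CO) method against a
    reference method in critically ill patients: CO computation from raw
    transthoracic-echo quantities (LVOT diameter, velocity-time integrals,
    heart rate) and from repeated thermodilution boluses; replicate-based
    precision and least significant change; Bland-Altman bias and limits of
    agreement with the Critchley percentage error; four-quadrant and
    half-circle polar-plot trending statistics with exclusion zones; and ROC
    analysis of percentage CO changes. Includes a synthetic paired-cohort
    generator with expected-summary oracles so every stage of the pipeline
    can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
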