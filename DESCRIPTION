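Package: gazedep
Title: Eye-Tracking Digital Biomarkers for Depression-Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a free-viewing emotional-face eye-tracking
    paradigm used to screen young adults at high risk of depression. Parses
    60 Hz gaze-coordinate session logs, computes area-of-interest digital
    biomarkers (fixation time, scan-path length, average scanning speed,
    attention level, attention shift, attention times), compares high- and
    low-risk groups (Levene's test, two-sample t-tests, Cohen's d, Pearson
    chi-square, Benjamini-Hochberg FDR), selects biomarkers by forward
    stepwise binary logistic regression, evaluates screening performance
    with ROC curves and AUC, and renders gaze heat maps. A synthetic-data
    module generates both feature-level two-group cohorts matched to
    published group statistics and stream-level fixation/saccade gaze
    sessions so that every stage is testable without participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    tibble,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
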