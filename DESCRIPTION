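Package: crmface
Title: Consistent Response Measurement from Facial Keypoint Trajectories
Version: 0.1.0
Authors@R:
    person("CRM", "Maintainers", email = "crmface@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how consistently a cohort of viewers moves
    their faces while watching the same emotionally evocative stimulus.
    Implements geometric normalization of tracked 66-point facial landmark
    trajectories (frontalization, affine registration to a reference face,
    part-wise similarity registration), keypoint-movement (KPM) vectors
    relative to a neutral frame, per-frame cross-subject consistency metrics
    (average/maximum t-statistic, per-keypoint Hotelling T-squared averages
    and maxima, and a PCA-reduced Hotelling T-squared), the FACS-based
    AU-consistency reference metric, and a cohort-analysis layer (percentile
    consistency classes, per-segment class-distribution tables, row-wise
    Kullback-Leibler comparison and linear-regression agreement). A synthetic
    cohort generator with known ground truth makes the whole pipeline
    testable without access-restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
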