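Package: fpvstag
Title: Frequency-Tagging EEG and Eye-Tracking Analysis of Scene Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying implicit neural discrimination of negative
    versus neutral visual scenes with fast periodic visual stimulation (FPVS)
    EEG and simultaneous eye tracking. Implements frequency-domain response
    quantification (signal-to-noise ratio, baseline-subtracted amplitude and
    Z-scores against neighbouring frequency bins), harmonic enumeration and
    significance-based harmonic selection, region-of-interest aggregation,
    calibration-aware probability weighting of fixations to areas of interest,
    and the cohort-level linear mixed-model pipeline with Tukey-corrected
    post-hoc contrasts. A synthetic-data generator emulates the oddball and
    multi-input stimulation paradigms, fixation streams and cohort covariate
    structure so every stage of the pipeline can be validated end-to-end
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
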