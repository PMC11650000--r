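Package: alphaslow
Title: Alpha Rhythm Slowing Analysis for Resting-State EEG/MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies slowing of the resting-state alpha rhythm from
    region-of-interest EEG or MEG time series.  Implements Welch relative
    band power, the slow (6-9 Hz) over fast (10-11 Hz) alpha power log
    ratio, hemispheric and global aggregation, cohort statistics
    (unpaired and paired t-tests, chi-square, Bonferroni correction,
    Anderson-Darling and Lilliefors normality checks) and ROC evaluation
    of the mean alpha ratio as a patient/control biomarker.  Ships a
    seeded synthetic-cohort generator (1/f background plus narrowband
    alpha oscillation with posterior-dominant topography) so the whole
    pipeline is testable without clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    nortest,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
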