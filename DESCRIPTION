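Package: neurostate
Title: Spatiotemporal Brain-State Dynamics for Rehabilitation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for characterising treatment-induced reorganisation of
    resting-state brain dynamics in clinical cohorts assessed before and
    after an intervention. Implements EEG microstate analysis
    (polarity-invariant modified k-means on global-field-power peak
    topographies, cross-validation based selection of the number of classes,
    back-fitting with minimum-duration smoothing, and temporal metrics),
    fMRI coactivation-pattern (CAP) analysis on ROI time series (cosine
    k-means over individual frames, Wilcoxon z-maps with network naming, and
    fractional occupancy / dwell time / appearance rate), responder
    stratification with normality-routed univariate tests, 2x2 mixed ANOVA
    with partial eta squared and Bonferroni simple effects, Spearman
    clinical correlation, and responder prediction by a support vector
    machine under repeated nested cross-validation. A synthetic-cohort
    generator with stored ground truth (semi-Markov microstate EEG, Markov
    CAP BOLD over the Yeo-7 networks, and coupled clinical scores) makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
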