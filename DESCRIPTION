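Package: stopsuite
Title: Desk-Scale Analysis Pipeline for Domain-General Inhibitory Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying domain-general inhibitory control over
    actions and thoughts at desk scale. Provides synthetic-data generators
    with planted ground truth (stop-signal trials from an independent race
    model under a 50 ms staircase, Think/No-Think recall with planted
    suppression-induced forgetting, ROI voxel patterns, peristimulus
    time-courses, and model-evidence matrices), stop-signal scoring by the
    integration method, conditionalized suppression-induced-forgetting
    scores, a robust correlation decision tree (boxplot/bagplot outliers,
    percentile-bend and MCD-skipped Spearman correlations), JZS one-sample
    Bayes factors, behavioural partial least squares with permutation and
    bootstrap inference, ROI time-course modulation analysis, cross-task
    multivoxel pattern classification with shrinkage LDA, and random-effects
    Bayesian model selection over a 73-model effective-connectivity space
    with family exceedance probabilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, MASS, mgcv, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
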