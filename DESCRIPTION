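Package: delaydisc
Title: Hierarchical Delay-Discounting Analysis for Antidepressant
    Discontinuation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits hyperbolic delay-discounting models to binary
    intertemporal choices (Kirby monetary choice questionnaire and an
    adaptive indifference-point task) by hierarchical empirical-Bayes
    estimation: per-participant maximum-a-posteriori fits under a
    population Gaussian prior learned by Expectation-Maximization, with
    Laplace posterior variances and a joint two-timepoint gain-score
    parameterization. Includes participant-level model evaluation
    (classification accuracy, right-tailed binomial exclusion test,
    McFadden's pseudo-R-squared), a simulator of the adaptive task, a
    synthetic remitted-depression cohort generator, and the downstream
    clinical statistics: gated parametric/non-parametric group
    comparisons with bootstrap effect-size intervals, Spearman
    correlations with bootstrap confidence intervals and Bonferroni
    correction, Cox proportional-hazards models of time to relapse,
    L1-regularized logistic relapse prediction with stratified
    cross-validation and balanced accuracy, linear mixed-effects models
    for discontinuation and symptom change, and noncentral-t post-hoc
    power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    lme4,
    lmerTest,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
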