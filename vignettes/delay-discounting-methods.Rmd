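---
title: "Hierarchical delay-discounting analysis: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical delay-discounting analysis: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific content of `delaydisc`: the choice
model, the hierarchical fitting procedure, the adaptive task simulator,
the evaluation and exclusion rules, the synthetic cohort generator, and
the downstream statistics — together with the assumptions, numerical
choices and limitations behind each.

## The choice model

A delayed reward of `R` currency units in `d` days has hyperbolic
subjective value `V = R / (1 + K d)`; `K` (1/day) is the participant's
discount rate. We use the standard single-parameter hyperbola, not the
generalized form with a curvature exponent: individual differences are
the target, and one parameter per person keeps them comparable. `K` is
log-normally distributed across people, so all fitting and statistics
operate on `log K` (natural logarithm; any base-10 reporting is a
display conversion).

Choices are stochastic. The probability of taking the immediate amount
`r` over the delayed `(R, d)` is a logistic sigmoid of the value
difference,

```
p(immediate) = sigma(beta * (r - V(R, d, K))),   sigma(x) = 1/(1 + exp(-x)),
```

with the sign convention that positive arguments favour the immediate
option. The inverse temperature `beta` (1/currency) is fitted per
participant on the log scale; it can be pinned to `exp(0) = 1` via
`fit_config(pin_log_beta = TRUE)` to recover an unscaled sigmoid.
Amounts enter in raw currency units; no magnitude normalisation is
applied. Numerically, probabilities and log-probabilities are computed
with `plogis()` (log-sum-exp-safe), and returned probabilities are
clamped into the open interval so no choice ever has probability exactly
0 or 1.

A useful deterministic consequence: each item has an indifference rate
`K* = (R - r) / (r d)`, and a noiseless agent takes the immediate reward
exactly when its `K` exceeds `K*`. On the packaged 27-item monetary
choice questionnaire (the standard published amounts, unitless currency)
the nine small-magnitude items split 4 above / 5 below `K* = 0.01`, so a
deterministic `K = 0.01` agent makes five immediate and four delayed
choices there — immediate precisely on the items whose `K*` lies below
its own rate.

## Hierarchical empirical-Bayes fitting

Per-participant parameters `theta_i = (log K_i, log beta_i)` receive a
population Gaussian prior `N(mu, Sigma)` whose hyperparameters are
learned from the data by Expectation-Maximization:

* **E-step** — for each participant, maximize
  `log-likelihood(theta) + log N(theta; mu, Sigma)` (BFGS with analytic
  gradients) and take a Laplace approximation at the mode: posterior
  covariance = inverse Hessian of the negative penalized objective.
* **M-step** — `mu` becomes the average MAP estimate; `Sigma` the
  average of centred-MAP outer products plus Laplace covariances.

Iteration stops when no hyperparameter moves by more than `em_tol`
(default 1e-3) or after `max_em_iter` (default 100). The empirical prior
regularises weakly constrained participants — an all-immediate responder
has no finite maximum-likelihood `log K`, but a finite MAP shrunk toward
the population mean. Fitting always uses each participant's concatenated
MCQ + adaptive trials as one likelihood.

Numerical and design choices, all exposed in `fit_config()`:

* Initialization: prior mean `(-4, 0[, 0])` on
  `(log K, log beta[, delta])`, covariance `2 I`. `exp(-4) ~ 0.018/day`
  sits mid-range of the MCQ item indifference rates, so the starting
  prior is uninformative about which side of the bank a participant
  falls on.
* Optimizer restarts: the first E-step starts each participant from the
  prior mean plus `n_restarts = 5` draws from the current prior (one
  seeded generator feeds all of them); later iterations warm-start from
  the previous MAP plus the prior mean. With a two-parameter smooth
  objective the warm start lands in the same basin, and the saving is
  roughly the restart count.
* Ties between equally good optima are broken by first-found.
* Covariance: full by default, `covariance_mode = "diagonal"` available;
  eigenvalues floored at 1e-4 (with a warning) so exchangeable or
  duplicated participants cannot collapse the prior.
* The Hessian at the MAP is ridge-regularized if numerically
  non-positive-definite, and the affected fit is flagged rather than
  silently accepted; non-convergence after all restarts likewise carries
  a flag, never an error mid-cohort.
* Determinism: `seed` is a required config field; identical data, seed
  and config give bit-identical results.

### Two-timepoint (gain-score) parameterization

Differencing two independently fitted noisy `log K` estimates adds their
errors. Instead, for participants assessed twice, the package fits
`(log K_MA1, delta, log beta)` jointly: MA1 trials use
`exp(log K_MA1)`, MA2 trials `exp(log K_MA1 + delta)`, and the
hierarchical prior spans all three coordinates. The fitted `delta` is
the gain score consumed downstream. `beta` is shared across timepoints
by default (the alternative was not identifiable as preferable from
anything in the study description; pinning is available). With
`pin_delta = TRUE` the parameterization collapses to the
single-timepoint model on pooled trials, which the tests verify as a
consistency check. Participants missing a timepoint are excluded from
this fit with a message.

## The adaptive task simulator

The study's adaptive questionnaire is described behaviourally — a
discount rate is re-estimated after each choice and the next offer is
placed at the estimated indifference point, until the estimate is stable
— but its internals are not printed. The package therefore implements a
declared substitute, not a reconstruction: a MAP-update staircase. Each
trial takes the next `(R, d)` from a fixed schedule (three magnitudes
30/55/80 crossed with five delays 7/20/50/90/160 days), offers
`r = round(V(R, d, exp(current log K)))` clipped to `[1, R - 1]` (whole
currency units), updates the MAP `log K` (inverse temperature pinned)
after the choice, and stops once the running estimate has varied by less
than `tol = 0.05` over the last `window = 3` trials, or at
`max_trials = 30`. Offers therefore always imply an indifference rate
equal to the running estimate up to rounding, and the final-estimate
bias for noiseless agents is bounded by the offer rounding granularity.
One consequence of the MAP update worth noting: a pathological
always-immediate responder does not oscillate but climbs monotonically
to the impatient boundary of the explored range, where the stability
rule may fire — the session is bounded either way.

## Evaluation and exclusion

Model quality is scored per participant on the concatenated tasks:

* **Accuracy** — fraction of trials where the model's
  higher-probability option matches the observed choice; exact-tie
  predictions (probability 0.5) count one half toward accuracy but are
  scored as incorrect for the test below, the conservative choice.
* **Exclusion** — the probability of `k` or more correct
  classifications out of `n` by chance is the exact right tail of
  `Binomial(n, 0.5)`; participants with `p > 0.05` are excluded. At
  `n = 27`, `k = 19` is the smallest retained count.
* **McFadden's pseudo-R²** — `1 - L_model / L_null` with the chance
  model (`p = 0.5` per trial) as the null, matching the standard the
  exclusion rule defines; a fitted-intercept null would be the main
  alternative and is deliberately not used.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, so the pipeline can be exercised, calibrated and
type-I-checked without any study data. Its defaults are the study
conditions: 97 patients and 54 controls across two sites; latent
`log K` Gaussian per group with control mean `log(0.0037) = -5.60`, SD
1.65, and a standardized patient shift of `d = 0.34` (placing the
patient mean at `log(0.0065)`, the two printed group-mean rates); a
47:50 randomization into discontinue-first vs discontinue-later arms;
latent test-retest correlation 0.72 across assessments; 17 dropouts; 35%
relapse over a 182-day follow-up; HAM-D scores in the remission range
correlated with baseline `log K` at Spearman 0.24; rating scales
(ERQ, BSCS, SWLS, ACE, CTQ with subscales, TLEQ, MWT-B, Daily Hassles)
as in-range noise except small configured CTQ physical-abuse (0.18) and
emotional-neglect (0.16) correlations. Choice data are simulated from
the softmax model at each participant's latent parameters — the full
MCQ bank plus an adaptive session per timepoint — with
`log beta ~ N(log 0.5, 0.5^2)`, chosen so that mean model accuracy on
refitted synthetic cohorts lands near the mid-80% range reported for
such tasks.

Implementation conventions: discrete scores (HAM-D, scales) come from
Gaussian copulas onto Poisson or scaled-Beta marginals; because heavy
ties attenuate rank correlations, the latent Pearson targets carry fixed
inflation factors calibrated once by a 200-seed pilot so the *realized*
Spearman correlations hit their configured targets in expectation
(realized means in that pilot: d 0.35, HAM-D rho 0.245, CTQ-PA 0.184,
CTQ-EN 0.161, retest 0.717, relapse 0.351). Correlation targets that
discretisation cannot carry are rejected at config validation. Relapse
is Bernoulli at the configured rate with a log-odds shift per SD of
baseline `log K` (zero by default — the null generator); relapse times
are uniform over follow-up by convention, with an exponential option,
since nothing in the study constrains the hazard shape. Dropouts are
flagged and excluded from relapse analyses but still carry both
timepoints' choices, a simplification relative to a real cohort where
early dropouts lack second assessments. All randomness flows from one
seed, with deterministic per-participant substreams for choice
simulation; the same seed reproduces output files byte for byte.

What passing tests on this generator do **not** show: robustness to real
response styles (lapses, side biases, item-order effects), site
differences beyond a label, non-Gaussian population structure in
`log K`, or informative dropout. Conclusions about real data rest on the
model, not on these simulations.

## Downstream statistics

* `gated_two_sample()` — Kolmogorov-Smirnov normality gates on
  standardized values (on paired differences for paired data) and a
  Bartlett equal-variance gate, both at fixed 0.05; Student's t when all
  pass, otherwise Wilcoxon signed-rank / rank-sum. The plain KS test is
  used (no Lilliefors correction; the original tooling is ambiguous on
  this, so the convention is documented rather than inferred).
  Zero-variance inputs route to the nonparametric path with a warning;
  all-zero paired differences return `p = 1`, `d = 0` under the
  zero-exclusion convention. Cohen's d uses the pooled-SD definition
  (standardized mean difference of paired differences when paired), with
  a 10,000-resample percentile bootstrap CI — a portable substitute for
  platform-specific CI tools. One-tailed directions are arguments, never
  inferred from the data.
* `spearman_with_bootstrap()` — mid-rank Spearman correlation,
  asymptotic p (ties-safe), percentile bootstrap CI over paired
  resamples, Bonferroni correction sized to the pre-specified family
  (8 instruments).
* `cox_fit()` — `survival::coxph` with Breslow tie handling (the
  original tie method is unstated; Breslow is declared).
* `lasso_relapse_cv()` — `glmnet` L1 logistic regression, strength
  chosen by stratified 10-fold cross-validated deviance at the
  deviance-minimizing lambda (not the 1-SE rule; documented choice),
  internal standardization, balanced accuracy = mean of per-class
  recalls. An all-zero solution is a constant majority-class predictor
  and scores exactly 0.5.
* Cross-validation independence: because hierarchical estimates share
  the population prior, fitting once and then cross-validating leaks
  information across folds. The pipeline's default `cv_mode = "strict"`
  re-learns the prior by EM on each training fold and MAP-fits held-out
  participants under it; `cv_mode = "single_fit"` reproduces the
  fit-once-then-CV procedure for replication.
* `lme_discontinuation()` / `lme_symptom_change()` —
  `lmerTest` mixed models (Satterthwaite df) for
  `log K ~ arm * timepoint` and
  `HAM-D ~ log K_MA1 * timepoint + arm * timepoint` with per-participant
  random effects. With only two timepoints a random slope plus intercept
  is weakly identified (the 2x2 within-person covariance cannot support
  all components), so the fitter attempts the slope model and falls back
  to random intercepts on failure or singularity, flagging
  `random_effects = "intercept_only"`.
* `posthoc_power_t()` — exact noncentral-t power,
  `ncp = d * sqrt(n1 n2 / (n1 + n2))`, `df = n1 + n2 - 2`; rounding
  happens only at presentation. At `n = (28, 52)` and two-tailed
  `alpha = 0.05` this gives 0.794 at `d = 0.66`, 0.947 at `d = 0.85`
  and 0.558 at `d = 0.5`.

## Problem sizes in the test suite

The suite exercises every stage at sizes chosen to keep the full run in
a few minutes while leaving Monte-Carlo envelopes meaningful: parameter
recovery on a 100-participant cohort with ~45-57 trials each; EM
determinism and ascent on 12 participants; type-I calibration at
1000 seeds (gated tests), 500 (Cox) and 200 (mixed models, latent-only
generation); generator calibration at 200 seeds; full-pipeline
byte-identity on a 56-participant cohort in strict CV mode. Bootstrap
counts are reduced inside simulation loops (the defaults remain 10,000
for single analyses).

## Known limitations

* The adaptive staircase is a behaviourally equivalent substitute for
  the study's adaptive procedure, not a re-implementation; absolute
  session lengths and offer grids differ from the original task.
* The two-timepoint prior treats `delta` as Gaussian and exchangeable
  across arms; a true arm-specific variance difference would be absorbed
  into the shared covariance.
* The chance-level null in McFadden's pseudo-R² makes values higher than
  a fitted-intercept null would give when choices are imbalanced;
  comparisons across studies should note the convention.
* Site is a label only; no site-stratified train/test replication is
  provided beyond generic fold assignment.
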