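# delaydisc

Hierarchical empirical-Bayes analysis of delay discounting in remitted
depression, built around the question of whether impatience for reward
predicts relapse after antidepressant discontinuation.

## The problem

Delay discounting describes how the subjective value of a reward falls
with the delay until its receipt. Under the standard single-parameter
hyperbola,

    V(R, d) = R / (1 + K * d),

a reward of `R` currency units available in `d` days is worth `V` today;
the discount rate `K` (1/day) indexes impatience. Because `K` is
log-normally distributed across people, analyses run on `log K`. A
discount rate of K = 0.0065/day, for example, makes 75 euros in 20 days
worth about 66 euros now; K = 0.0037/day makes it worth about 70.

Binary choices between a smaller-immediate and a larger-delayed reward —
the 27-item Kirby monetary choice questionnaire plus an adaptive task
that re-estimates `K` after every choice and offers the next immediate
amount at the current indifference point — are linked to the model by a
softmax: the probability of taking the immediate reward is
`sigma(beta * (r - V(R, d, K)))`, with inverse temperature `beta`.
Per-participant parameters `(log K, log beta)` are estimated by
maximum-a-posteriori fitting under a population Gaussian prior learned
by Expectation-Maximization (empirical Bayes), with Laplace posterior
variances; a joint two-timepoint parameterization estimates the change
in `log K` between assessments (`delta`, the gain score) concurrently
with baseline rather than by differencing noisy estimates.

The package is aimed at computational-psychiatry researchers who want
this pipeline — task banks, choice model, hierarchical fitting, model
evaluation and exclusion, and the downstream clinical statistics — as
tested, reusable functions, together with a synthetic cohort generator
that reproduces the statistical structure of a two-site, two-timepoint
remitted-depression discontinuation study (group shift in `log K`,
symptom correlation, test-retest stability, ~35% relapse), so that every
stage can be exercised and calibrated without the original data.

## Worked example

```r
library(delaydisc)

cfg   <- synthetic_config(n_patients = 24, n_controls = 16,
                          dropout_n = 4, seed = 7)
study <- generate_cohort(cfg)          # cohort.csv + choices.csv schemas
ma1   <- study$choices[study$choices$timepoint == "MA1", ]

fit <- em_fit(ma1, fit_config(seed = 7))
fit
#> Hierarchical single-timepoint empirical-Bayes fit
#>   participants: 40
#>   EM iterations: 14 (converged)
#>   prior mean: log_k=-4.778, log_beta=-0.189

round(attr(evaluate_cohort(fit, ma1), "summary"), 3)
#>  mean_accuracy mean_pseudo_r2     n_excluded
#>          0.898          0.700          0.000

est <- merge(fit$estimates, study$cohort, by = "participant_id")
gated_two_sample(est$log_k_map[est$group == "patient"],
                 est$log_k_map[est$group == "control"],
                 alternative = "greater", n_boot = 2000)
#> rank_sum: statistic = 251.000, p = 0.05315 (greater)
#> Cohen's d = 0.661 [0.104, 1.241]
```

The EM fit recovers a population prior near the generating distribution;
the model classifies ~90% of the simulated choices correctly (so no
participant is excluded by the binomial criterion), and the gated group
comparison — which routed to the rank-sum test because this small sample
failed the normality gate — estimates higher discounting in the patient
group. `run_analysis_pipeline()` chains all of this (including gain
scores, Cox models of days-to-relapse, lasso relapse prediction with
stratified cross-validation, and the mixed-effects models) into one
seeded, machine-readable results table. Post-hoc power for the relapse
contrast is available directly:

```r
round(posthoc_power_t(0.66, 28, 52), 3)
#> [1] 0.794
```

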