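diffuse_prior <- function() {
  prior_hyper(c(log_k = -4, log_beta = 0), diag(c(9, 4)))
}

test_that("an overwhelming prior dominates the MAP", {
  tr <- sim_mcq_trials(-6, log(3), seed = 2)
  tight <- prior_hyper(c(log_k = -3.2, log_beta = 0.4), diag(1e-6, 2))
  set.seed(1)
  fit <- map_fit(tr, tight, n_restarts = 2)
  expect_equal(unname(fit$par), c(-3.2, 0.4), tolerance = 1e-2)
})

test_that("the MAP agrees with a grid-search oracle on dense data", {
  tr <- sim_mcq_trials(-5, log(3), n_rep = 8, seed = 3) # 216 trials
  set.seed(2)
  fit <- map_fit(tr, diffuse_prior())
  expect_true(fit$converged)
  expect_equal(unname(fit$par["log_k"]), -5, tolerance = 0.2)
  # oracle: profile over log_k at the fitted log_beta
  grid <- seq(-7, -3, by = 0.01)
  obj <- vapply(grid, function(lk) {
    choice_loglik(tr, lk, fit$par["log_beta"]) +
      delaydisc:::dmvn_log(c(log_k = lk,
                             log_beta = unname(fit$par["log_beta"])),
                           diffuse_prior())
  }, numeric(1))
  expect_equal(grid[which.max(obj)], unname(fit$par["log_k"]),
               tolerance = 0.02)
  # Laplace variance is positive and finite
  expect_true(all(is.finite(fit$laplace_var)) && all(fit$laplace_var > 0))
})

test_that("degenerate all-immediate responders stay finite under the prior", {
  bank <- mcq_item_bank()
  tr <- data.frame(participant_id = "x", timepoint = "MA1",
                   task_tag = "mcq", trial_index = 1:27,
                   r_immediate = bank$r_immediate,
                   R_delayed = bank$R_delayed,
                   delay_days = bank$delay_days, choice = "immediate")
  set.seed(3)
  fit <- map_fit(tr, diffuse_prior())
  expect_true(all(is.finite(fit$par)))
  # shrunk back toward the prior: within a few prior SDs of the mean
  expect_lt(abs(fit$par["log_k"] - (-4)), 3 * 3)
})

test_that("MAP estimates shrink monotonically toward the prior mean", {
  tr <- sim_mcq_trials(-6.5, log(2), seed = 4)
  mean0 <- c(log_k = -3, log_beta = 0)
  dist <- vapply(c(4, 1, 0.25, 0.04, 0.004), function(s2) {
    set.seed(4)
    fit <- map_fit(tr, prior_hyper(mean0, diag(s2, 2)), n_restarts = 2)
    abs(unname(fit$par["log_k"] - mean0["log_k"]))
  }, numeric(1))
  expect_true(all(diff(dist) < 1e-6))
})

test_that("EM with exchangeable participants collapses to a common estimate", {
  tr <- sim_mcq_trials(-4.8, log(2), seed = 6, id = "P001")
  ch <- do.call(rbind, lapply(sprintf("P%03d", 1:4), function(id) {
    tr$participant_id <- id
    tr
  }))
  fit <- suppressWarnings(em_fit(ch, fit_config(seed = 10)))
  expect_equal(diff(range(fit$estimates$log_k_map)), 0, tolerance = 1e-3)
  # the population spread collapses to the shared posterior uncertainty
  expect_lt(max(eigen(fit$prior$cov)$values), 1)
  expect_gte(min(eigen(fit$prior$cov)$values), 1e-4 - 1e-8)
  expect_error(em_fit(tr, fit_config(seed = 1)), "at least 2")
})

test_that("the EM objective ascends and the fit is deterministic", {
  set.seed(8)
  lk <- rnorm(12, -4.5, 1)
  ch <- sim_group_trials(lk, seed = 2)
  cfg <- fit_config(seed = 7)
  fit1 <- em_fit(ch, cfg)
  expect_true(all(diff(fit1$objective_trace) > -1e-6))
  expect_lte(fit1$n_iter, cfg$max_em_iter)
  fit2 <- em_fit(ch, cfg)
  expect_identical(fit1$estimates, fit2$estimates)
  expect_identical(fit1$prior, fit2$prior)
})

test_that("fitting is invariant to trial order (concatenation contract)", {
  set.seed(9)
  lk <- rnorm(6, -4.5, 1)
  ch <- sim_group_trials(lk, seed = 3)
  half <- ch$trial_index <= 27
  reordered <- rbind(ch[!half, ], ch[half, ])
  f1 <- em_fit(ch, fit_config(seed = 5))
  f2 <- em_fit(reordered, fit_config(seed = 5))
  expect_equal(f1$estimates$log_k_map, f2$estimates$log_k_map,
               tolerance = 1e-6)
})

test_that("EM recovers the generating population on a medium cohort", {
  g <- generate_cohort(synthetic_config(n_patients = 2, n_controls = 38,
                                        dropout_n = 0,
                                        logk_mean_control = -4.5,
                                        logk_sd = 1, group_effect_d = 0,
                                        seed = 31))
  ma1 <- g$choices[g$choices$timepoint == "MA1", ]
  fit <- em_fit(ma1, fit_config(seed = 32))
  truth <- g$cohort$true_log_k_ma1[match(fit$estimates$participant_id,
                                         g$cohort$participant_id)]
  expect_equal(unname(fit$prior$mean["log_k"]), mean(truth),
               tolerance = 0.25)
  expect_gt(cor(truth, fit$estimates$log_k_map, method = "spearman"), 0.9)
})

test_that("two-timepoint fitting shrinks delta to zero for identical data", {
  tr1 <- sim_mcq_trials(-4.5, log(2), seed = 12, id = "P001")
  tr2 <- tr1
  tr2$timepoint <- "MA2"
  ch <- do.call(rbind, lapply(sprintf("P%03d", 1:6), function(id) {
    out <- rbind(tr1, tr2)
    out$participant_id <- id
    out
  }))
  fit <- em_fit_two_timepoint(ch, fit_config(seed = 13))
  prior_sd_delta <- sqrt(fit$prior$cov["delta", "delta"])
  expect_true(all(abs(fit$estimates$delta) < pmax(prior_sd_delta, 0.05)))
})

test_that("participants missing a timepoint are excluded with a notice", {
  ch <- rbind(sim_mcq_trials(-4, log(2), seed = 14, id = "A"),
              sim_mcq_trials(-5, log(2), seed = 15, id = "B"),
              sim_mcq_trials(-4, log(2), seed = 16, id = "A",
                             timepoint = "MA2"),
              sim_mcq_trials(-5, log(2), seed = 17, id = "C"),
              sim_mcq_trials(-5, log(2), seed = 18, id = "C",
                             timepoint = "MA2"))
  expect_message(fit <- em_fit_two_timepoint(ch, fit_config(seed = 19)),
                 "missing a timepoint")
  expect_setequal(fit$estimates$participant_id, c("A", "C"))
})

test_that("pinning delta reproduces the single-timepoint parameterization", {
  tr <- rbind(sim_mcq_trials(-5.2, log(2), seed = 20, id = "Z"),
              sim_mcq_trials(-5.2, log(2), seed = 21, id = "Z",
                             timepoint = "MA2"))
  pr2 <- prior_hyper(c(log_k_ma1 = -4, log_beta = 0), diag(c(4, 2)))
  pr1 <- prior_hyper(c(log_k = -4, log_beta = 0), diag(c(4, 2)))
  f2 <- map_fit(tr, pr2, n_restarts = 0)
  f1 <- map_fit(tr, pr1, n_restarts = 0)
  expect_equal(unname(f2$par[["log_k_ma1"]]), unname(f1$par[["log_k"]]),
               tolerance = 1e-5)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("a true discontinuation shift in delta is recovered", {
  g <- generate_cohort(synthetic_config(n_patients = 30, n_controls = 1,
                                        dropout_n = 0,
                                        discontinuation_effect = 0.5,
                                        seed = 41))
  pat_ids <- g$cohort$participant_id[g$cohort$group == "patient"]
  ch <- g$choices[g$choices$participant_id %in% pat_ids, ]
  fit <- em_fit_two_timepoint(ch, fit_config(seed = 42))
  arm <- g$cohort$arm[match(fit$estimates$participant_id,
                            g$cohort$participant_id)]
  gap <- mean(fit$estimates$delta[arm == "MA1-D-MA2"]) -
    mean(fit$estimates$delta[arm == "MA1-MA2-D"])
  true_gap <- with(g$cohort[g$cohort$group == "patient", ],
                   mean((true_log_k_ma2 - true_log_k_ma1)[arm == "MA1-D-MA2"]) -
                     mean((true_log_k_ma2 - true_log_k_ma1)[arm == "MA1-MA2-D"]))
  expect_equal(gap, true_gap, tolerance = 0.3)
  expect_gt(gap, 0.1)
})

test_that("fit results serialize and read back", {
  ch <- sim_group_trials(c(-4, -5), seed = 4)
  fit <- em_fit(ch, fit_config(seed = 20, max_em_iter = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$log_k_map, fit$estimates$log_k_map, tolerance = 1e-9)
})

test_that("fit configs load from flat YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "max_em_iter: 7", "pin_log_beta: true",
               "covariance_mode: diagonal"), path)
  cfg <- read_fit_config(path)
  expect_s3_class(cfg, "fit_config")
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$max_em_iter, 7)
  expect_true(cfg$pin_log_beta)
  expect_equal(cfg$covariance_mode, "diagonal")
})
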