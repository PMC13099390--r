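# Synthetic two-site, two-timepoint remitted-MDD cohort generator: latent
# log-normal discount rates with a patient-vs-control shift, test-retest
# stability, a rank correlation between discounting and depressive
# symptoms, ~35% relapse over follow-up, and simulated choice data (full
# MCQ bank plus an adaptive session) at each participant's latent
# parameters. It gives every downstream stage a testable stand-in with the
# statistical structure the analysis assumes.

# Copula inflation factors: latent Pearson correlations are inflated so
# that the realized Spearman correlation on the discretized scores hits
# the configured target in expectation (fixed once by pilot simulation).
.hamd_inflation <- 0.93
.scale_inflation <- 1.05

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 97
#' patients and 54 controls; control mean discount rate K = 0.0037/day
#' (log K = -5.60) with SD 1.65 on the log scale, and a standardized
#' patient shift of d = 0.34 (putting the patient mean at K = 0.0065);
#' rank correlation 0.24 between baseline log K and HAM-D; test-retest
#' correlation 0.72 of latent log K across the two assessments; 35%
#' relapse among the 80 patients retained through a 182-day follow-up
#' after 17 dropouts; a 47:50 split between the discontinue-first
#' (MA1-D-MA2) and discontinue-later (MA1-MA2-D) arms.
#'
#' @param n_patients,n_controls Group sizes.
#' @param logk_mean_control Control-group mean of latent log K.
#' @param logk_sd SD of latent log K (both groups).
#' @param group_effect_d Standardized patient-minus-control shift in
#'   latent log K.
#' @param rho_hamd Target Spearman correlation between baseline log K and
#'   HAM-D (pooled groups).
#' @param test_retest_r Correlation of latent log K across MA1/MA2.
#' @param relapse_rate Relapse probability during follow-up at the mean
#'   discount rate.
#' @param discontinuation_effect True change in mean log K at MA2 caused
#'   by discontinuation (MA1-D-MA2 arm only).
#' @param relapse_logk_effect Log-odds change in relapse per SD of
#'   baseline log K.
#' @param dropout_n Number of patients dropping out (excluded from
#'   relapse analyses).
#' @param beta_mean,beta_sd Softmax inverse-temperature distribution:
#'   `log_beta ~ N(log(beta_mean), beta_sd^2)` (1/currency).
#' @param followup_days Follow-up horizon in days.
#' @param relapse_time_dist Distribution of relapse times given relapse:
#'   `"uniform"` over the follow-up or `"exponential"` (truncated).
#' @param hamd_mean_patient,hamd_mean_control Mean baseline HAM-D counts.
#' @param hamd_discontinuation_effect Added mean HAM-D at MA2 after
#'   discontinuation (MA1-D-MA2 arm).
#' @param hamd_drift Added mean HAM-D at MA2 in the still-medicated arm.
#' @param hamd_logk_time_effect Change in expected MA2 HAM-D per unit of
#'   baseline log K (a discounting-by-time interaction; 0 by default).
#' @param rho_ctq_pa,rho_ctq_en Target Spearman correlations of log K
#'   with the CTQ physical-abuse and emotional-neglect subscales; all
#'   other scales are uncorrelated noise.
#' @param arm_ratio Proportion of patients randomized to MA1-D-MA2.
#' @param seed Integer seed; one generator drives all randomness, with
#'   per-participant substreams for choice simulation.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 97, n_controls = 54,
                             logk_mean_control = log(0.0037),
                             logk_sd = 1.65, group_effect_d = 0.34,
                             rho_hamd = 0.24, test_retest_r = 0.72,
                             relapse_rate = 0.35,
                             discontinuation_effect = 0,
                             relapse_logk_effect = 0, dropout_n = 17,
                             beta_mean = 0.5, beta_sd = 0.5,
                             followup_days = 182,
                             relapse_time_dist = c("uniform", "exponential"),
                             hamd_mean_patient = 1.8,
                             hamd_mean_control = 0.4,
                             hamd_discontinuation_effect = 1.4,
                             hamd_drift = 0.2,
                             hamd_logk_time_effect = 0,
                             rho_ctq_pa = 0.18, rho_ctq_en = 0.16,
                             arm_ratio = 47 / 97, seed = 1) {
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              logk_mean_control = logk_mean_control, logk_sd = logk_sd,
              group_effect_d = group_effect_d, rho_hamd = rho_hamd,
              test_retest_r = test_retest_r, relapse_rate = relapse_rate,
              discontinuation_effect = discontinuation_effect,
              relapse_logk_effect = relapse_logk_effect,
              dropout_n = dropout_n, beta_mean = beta_mean,
              beta_sd = beta_sd, followup_days = followup_days,
              relapse_time_dist = match.arg(relapse_time_dist),
              hamd_mean_patient = hamd_mean_patient,
              hamd_mean_control = hamd_mean_control,
              hamd_discontinuation_effect = hamd_discontinuation_effect,
              hamd_drift = hamd_drift,
              hamd_logk_time_effect = hamd_logk_time_effect,
              rho_ctq_pa = rho_ctq_pa, rho_ctq_en = rho_ctq_en,
              arm_ratio = arm_ratio, seed = as.integer(seed))
  stopifnot(n_patients > 1, n_controls > 0, logk_sd > 0, beta_mean > 0,
            beta_sd >= 0, followup_days > 1, arm_ratio > 0, arm_ratio < 1)
  if (dropout_n < 0 || dropout_n >= n_patients) {
    stop("dropout_n must lie in [0, n_patients)", call. = FALSE)
  }
  if (relapse_rate <= 0 || relapse_rate >= 1) {
    stop("relapse_rate must lie in (0, 1)", call. = FALSE)
  }
  for (r in c("rho_hamd", "test_retest_r", "rho_ctq_pa", "rho_ctq_en")) {
    if (abs(cfg[[r]]) >= 1) stop(r, " must satisfy |r| < 1", call. = FALSE)
  }
  # heavily tied discretized scores cannot carry arbitrarily strong rank
  # correlations: the low-count HAM-D saturates well below |rho| = 1
  if (abs(rho_hamd) * .hamd_inflation >= 0.9 ||
      max(abs(rho_ctq_pa), abs(rho_ctq_en)) * .scale_inflation >= 0.95) {
    stop("correlation target infeasible under score discretisation",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Deterministic per-participant substream seed (kept below 2^31).
substream_seed <- function(seed, i, salt = 0) {
  as.integer((as.numeric(seed) * 1009 + i * 7919 + salt * 104729) %%
               2147483647)
}

# Gaussian copula quantile map onto a Poisson count, clipped.
copula_pois <- function(z, lambda, cap) {
  pmin(stats::qpois(stats::pnorm(z), pmax(lambda, 0.05)), cap)
}

#' Generate a complete synthetic study dataset
#'
#' Draws latent per-participant discounting parameters and clinical
#' outcomes under a [synthetic_config()], and (optionally) simulates the
#' full choice data: the 27-item MCQ plus an adaptive session per
#' participant and timepoint (patients at MA1 and MA2, controls at MA1).
#' Latent truths are carried in `true_*` columns of the cohort table for
#' calibration and recovery testing; the canonical I/O schema ignores
#' them.
#'
#' @param config A [synthetic_config()].
#' @param choices If `FALSE`, skip choice simulation (latent structure
#'   only; much faster for Monte-Carlo calibration).
#' @return A list with elements `cohort` (participant records with scale
#'   columns and latent truths) and `choices` (canonical choice trials,
#'   or `NULL`).
#' @export
generate_cohort <- function(config, choices = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  np <- config$n_patients; nc <- config$n_controls
  mu_c <- config$logk_mean_control
  mu_p <- mu_c + config$group_effect_d * config$logk_sd

  id <- c(sprintf("P%03d", seq_len(np)), sprintf("C%03d", seq_len(nc)))
  group <- rep(c("patient", "control"), c(np, nc))
  site <- c(rep(c("A", "B"), c(round(np * 71 / 97), np - round(np * 71 / 97))),
            rep(c("A", "B"), c(round(nc * 32 / 54), nc - round(nc * 32 / 54))))
  mu_g <- ifelse(group == "patient", mu_p, mu_c)

  logk1 <- stats::rnorm(np + nc, mu_g, config$logk_sd)
  z1 <- (logk1 - mu_g) / config$logk_sd

  # arms: exact split among patients, randomized assignment
  n_d <- round(np * config$arm_ratio)
  arm <- rep("none", np + nc)
  arm[seq_len(np)] <- sample(rep(c("MA1-D-MA2", "MA1-MA2-D"),
                                 c(n_d, np - n_d)))

  # MA2 latent log K: regression toward the group mean at the test-retest
  # correlation, plus any true discontinuation effect
  r <- config$test_retest_r
  logk2 <- rep(NA_real_, np + nc)
  pat <- group == "patient"
  logk2[pat] <- mu_g[pat] + r * (logk1[pat] - mu_g[pat]) +
    sqrt(1 - r^2) * config$logk_sd * stats::rnorm(np) +
    config$discontinuation_effect * (arm[pat] == "MA1-D-MA2")

  log_beta <- stats::rnorm(np + nc, log(config$beta_mean), config$beta_sd)

  # dropouts: excluded from relapse analyses
  dropped <- rep(FALSE, np + nc)
  dropped[sample(seq_len(np), config$dropout_n)] <- TRUE

  # relapse: Bernoulli at the configured rate, log-odds shifted by the
  # standardized baseline log K
  relapsed <- rep(NA, np + nc)
  days <- rep(NA_real_, np + nc)
  at_risk <- pat & !dropped
  p_rel <- stats::plogis(stats::qlogis(config$relapse_rate) +
                           config$relapse_logk_effect * z1)
  relapsed[at_risk] <- stats::runif(sum(at_risk)) < p_rel[at_risk]
  rel <- !is.na(relapsed) & relapsed
  if (config$relapse_time_dist == "uniform") {
    days[rel] <- ceiling(stats::runif(sum(rel), 0, config$followup_days))
  } else {
    raw <- stats::qexp(stats::runif(sum(rel)) *
                         stats::pexp(config$followup_days,
                                     3 / config$followup_days),
                       3 / config$followup_days)
    days[rel] <- pmax(1, ceiling(raw))
  }
  days[at_risk & !rel] <- config$followup_days

  # HAM-D via a Gaussian copula onto Poisson counts (remission range)
  rho_l <- config$rho_hamd * .hamd_inflation
  h1 <- rho_l * z1 + sqrt(1 - rho_l^2) * stats::rnorm(np + nc)
  lam1 <- ifelse(pat, config$hamd_mean_patient, config$hamd_mean_control)
  hamd_ma1 <- copula_pois(h1, lam1, 6)
  h2 <- rho_l * z1 + sqrt(1 - rho_l^2) * stats::rnorm(np + nc)
  lam2 <- config$hamd_mean_patient + config$hamd_drift +
    (config$hamd_discontinuation_effect - config$hamd_drift) *
      (arm == "MA1-D-MA2") +
    config$hamd_logk_time_effect * (logk1 - mu_p)
  hamd_ma2 <- rep(NA_real_, np + nc)
  hamd_ma2[pat] <- copula_pois(h2[pat], lam2[pat], 17)

  cohort <- data.frame(
    participant_id = id, site = site, group = group, arm = arm,
    relapsed = relapsed, days_to_event = days, dropped_out = dropped,
    hamd_ma1 = hamd_ma1, hamd_ma2 = hamd_ma2,
    true_log_k_ma1 = logk1, true_log_k_ma2 = logk2,
    true_log_beta = log_beta, stringsAsFactors = FALSE)
  cohort <- generate_scales(cohort, config)
  validate_cohort(cohort)

  trial_tab <- NULL
  if (choices) {
    bank <- mcq_item_bank()
    sim_one <- function(i, logk, tp, salt) {
      set.seed(substream_seed(config$seed, i, salt))
      p <- p_immediate(bank$r_immediate, bank$R_delayed, bank$delay_days,
                       logk, log_beta[i])
      mcq <- data.frame(
        participant_id = id[i], timepoint = tp, task_tag = "mcq",
        trial_index = seq_len(nrow(bank)),
        r_immediate = bank$r_immediate, R_delayed = bank$R_delayed,
        delay_days = bank$delay_days,
        choice = ifelse(stats::runif(nrow(bank)) < p, "immediate", "delayed"),
        stringsAsFactors = FALSE)
      ses <- run_session(softmax_agent(logk, log_beta[i]),
                         participant_id = id[i], timepoint = tp)
      rbind(mcq, ses$trials)
    }
    parts <- vector("list", 2 * (np + nc))
    for (i in seq_len(np + nc)) {
      parts[[2 * i - 1]] <- sim_one(i, logk1[i], "MA1", salt = 1)
      if (pat[i]) parts[[2 * i]] <- sim_one(i, logk2[i], "MA2", salt = 2)
    }
    trial_tab <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    rownames(trial_tab) <- NULL
    validate_choices(trial_tab)
  }
  list(cohort = cohort, choices = trial_tab)
}

# Scale definitions: instrument score ranges and marginal shapes.
scale_defs <- function() {
  data.frame(
    name = c("erq", "bscs", "swls", "ace", "ctq_ea", "ctq_pa", "ctq_sa",
             "ctq_en", "ctq_pn", "tleq", "mwtb", "daily_hassles"),
    min = c(10, 13, 5, 0, 5, 5, 5, 5, 5, 0, 0, 0),
    max = c(70, 65, 35, 10, 25, 25, 25, 25, 25, 23, 37, 50),
    a = c(3, 3, 3, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 4, 2),
    b = c(3, 3, 3, 4, 4, 4, 4, 4, 4, 4, 2, 3),
    stringsAsFactors = FALSE)
}

#' Add rating-scale columns to participant records
#'
#' Generates ERQ, BSCS, SWLS, ACE, CTQ subscales (plus their total),
#' TLEQ, MWT-B and Daily Hassles totals within their documented
#' instrument ranges. All scales are uncorrelated noise except the CTQ
#' physical-abuse and emotional-neglect subscales, which receive the
#' configured small rank correlations with baseline log K via a Gaussian
#' copula.
#'
#' @param records Cohort `data.frame` carrying `true_log_k_ma1` and
#'   `group`.
#' @param config A [synthetic_config()].
#' @return `records` with scale columns appended.
#' @export
generate_scales <- function(records, config) {
  stopifnot("true_log_k_ma1" %in% names(records))
  n <- nrow(records)
  mu_g <- ifelse(records$group == "patient",
                 config$logk_mean_control +
                   config$group_effect_d * config$logk_sd,
                 config$logk_mean_control)
  z <- (records$true_log_k_ma1 - mu_g) / config$logk_sd
  defs <- scale_defs()
  targets <- c(ctq_pa = config$rho_ctq_pa, ctq_en = config$rho_ctq_en)
  for (j in seq_len(nrow(defs))) {
    rho <- unname(targets[defs$name[j]])
    rho <- if (is.na(rho)) 0 else rho * .scale_inflation
    lat <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    q <- stats::qbeta(stats::pnorm(lat), defs$a[j], defs$b[j])
    records[[defs$name[j]]] <- defs$min[j] +
      round(q * (defs$max[j] - defs$min[j]))
  }
  records$ctq <- records$ctq_ea + records$ctq_pa + records$ctq_sa +
    records$ctq_en + records$ctq_pn
  records
}
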