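# Pre-registered downstream statistics: gated group comparisons with
# bootstrap effect-size intervals, Spearman correlations with bootstrap
# CIs and Bonferroni correction, Cox proportional hazards on days to
# relapse, L1-regularized logistic relapse prediction with stratified CV
# and balanced accuracy, linear mixed-effects models, and noncentral-t
# post-hoc power.

#' Normality/equal-variance-gated two-sample comparison
#'
#' Runs the assumption gates at the 0.05 level -- a Kolmogorov-Smirnov
#' test of normality on standardized values (on the paired differences
#' for paired data) and, for independent samples, a Bartlett test of
#' equal variance -- and selects Student's t-test when all gates pass,
#' otherwise the Wilcoxon signed-rank (paired) or rank-sum (independent)
#' test. Always reports Cohen's d (pooled-SD definition; for paired data
#' the standardized mean difference of the paired differences) with a
#' percentile bootstrap confidence interval, plus means/SDs and
#' medians/IQRs per group.
#'
#' @param x,y Numeric samples (each n >= 3; equal lengths when paired).
#' @param paired Paired comparison?
#' @param alternative `"two.sided"`, `"greater"` (x tends larger), or
#'   `"less"`; one-tailed directions must come from the hypothesis, never
#'   from the data.
#' @param n_boot Bootstrap resamples for the effect-size CI (0 skips the
#'   CI).
#' @param conf_level CI level.
#' @return A list of class `comparison_result`: `test_used`, `statistic`,
#'   `df`, `p`, `alternative`, `cohens_d`, `d_ci`, `gates` (gate
#'   p-values), and per-group `summaries`.
#' @export
gated_two_sample <- function(x, y, paired = FALSE,
                             alternative = c("two.sided", "greater", "less"),
                             n_boot = 10000, conf_level = 0.95) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired && length(x) != length(y)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (length(x) < 3 || length(y) < 3) {
    stop("each sample needs n >= 3", call. = FALSE)
  }
  ks_p <- function(v) {
    if (stats::sd(v) == 0) return(0) # degenerate: fail the gate
    suppressWarnings(stats::ks.test((v - mean(v)) / stats::sd(v),
                                    "pnorm")$p.value)
  }
  zero_var <- (paired && stats::sd(x - y) == 0) ||
    (!paired && (stats::sd(x) == 0 || stats::sd(y) == 0))
  if (zero_var) warning("zero-variance input: using non-parametric test",
                        call. = FALSE)
  if (paired) {
    gates <- c(ks_diff = ks_p(x - y))
  } else {
    gates <- c(ks_x = ks_p(x), ks_y = ks_p(y),
               bartlett = if (zero_var) 0 else
                 stats::bartlett.test(list(x, y))$p.value)
  }
  use_t <- !zero_var && all(gates > 0.05)

  d_fun <- function(x, y) {
    if (paired) {
      d <- x - y
      if (stats::sd(d) == 0) return(0)
      mean(d) / stats::sd(d)
    } else {
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                    (length(y) - 1) * stats::var(y)) /
                   (length(x) + length(y) - 2))
      if (sp == 0) return(0)
      (mean(x) - mean(y)) / sp
    }
  }
  d <- d_fun(x, y)
  d_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      if (paired) {
        i <- sample.int(length(x), replace = TRUE)
        d_fun(x[i], y[i])
      } else {
        d_fun(x[sample.int(length(x), replace = TRUE)],
              y[sample.int(length(y), replace = TRUE)])
      }
    }, numeric(1))
    a <- (1 - conf_level) / 2
    d_ci <- unname(stats::quantile(boot, c(a, 1 - a), na.rm = TRUE))
  }

  if (use_t) {
    tt <- stats::t.test(x, y, paired = paired, var.equal = TRUE,
                        alternative = alternative)
    test_used <- "student_t"
    statistic <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    test_used <- if (paired) "wilcoxon_signed_rank" else "rank_sum"
    if (paired && all(x - y == 0)) {
      # all-zero differences: signed-rank has no information
      statistic <- NA_real_; df <- NA_real_; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                                alternative = alternative,
                                                exact = FALSE))
      statistic <- unname(wt$statistic); df <- NA_real_; p <- wt$p.value
    }
  }
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        median = stats::median(v),
                        iqr = stats::IQR(v), n = length(v))
  structure(list(test_used = test_used, statistic = statistic, df = df,
                 p = p, alternative = alternative, cohens_d = d,
                 d_ci = d_ci, gates = gates,
                 summaries = list(x = summ(x), y = summ(y))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g (%s)\n", x$test_used,
              x$statistic, x$p, x$alternative))
  cat(sprintf("Cohen's d = %.3f [%.3f, %.3f]\n", x$cohens_d,
              x$d_ci[1], x$d_ci[2]))
  invisible(x)
}

#' Spearman correlation with bootstrap CI and Bonferroni correction
#'
#' Rank correlation with mid-ranks for ties; the confidence interval is a
#' percentile bootstrap over paired resamples; the Bonferroni-corrected
#' p-value is `min(1, n_comparisons * p)`.
#'
#' @param x,y Paired numeric vectors (NA pairs dropped; n >= 5).
#' @param n_boot Bootstrap iterations (default 10,000).
#' @param n_comparisons Number of pre-specified comparisons in the
#'   family.
#' @param conf_level CI level.
#' @return A list of class `correlation_result`: `rho`, `p`,
#'   `p_bonferroni`, `rho_ci`, `n`.
#' @export
spearman_with_bootstrap <- function(x, y, n_boot = 10000,
                                    n_comparisons = 1, conf_level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need n >= 5 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                        exact = FALSE)$p.value)
  rho_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(x), replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
      stats::cor(x[i], y[i], method = "spearman")
    }, numeric(1))
    a <- (1 - conf_level) / 2
    rho_ci <- unname(stats::quantile(boot, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(rho = rho, p = p,
                 p_bonferroni = min(1, n_comparisons * p),
                 rho_ci = rho_ci, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f [%.3f, %.3f], p = %.4g (Bonferroni %.4g), n = %d\n",
              x$rho, x$rho_ci[1], x$rho_ci[2], x$p, x$p_bonferroni, x$n))
  invisible(x)
}

#' Cox proportional hazards model of time to relapse
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling via
#' `survival::coxph`. Supports both study specifications: baseline log K
#' alone, or baseline and post-discontinuation log K jointly.
#'
#' @param times Days to relapse or censoring (> 0).
#' @param events Logical event indicator (>= 1 event required).
#' @param covariates `data.frame` (or vector) of covariates.
#' @param robust Use robust standard errors?
#' @return A list of class `survival_fit`: `coefficients`, `se`, `z`,
#'   `p`, `n`, `n_events`, `ties`, and the underlying `model`.
#' @export
cox_fit <- function(times, events, covariates, robust = FALSE) {
  if (!is.data.frame(covariates)) covariates <- data.frame(x = covariates)
  ok <- stats::complete.cases(covariates) & !is.na(times) & !is.na(events)
  times <- times[ok]; events <- events[ok]
  covariates <- covariates[ok, , drop = FALSE]
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (sum(events) < 1) stop("at least one event is required", call. = FALSE)
  dat <- cbind(data.frame(.time = times, .event = as.integer(events)),
               covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow", robust = robust)
  s <- summary(fit)
  co <- s$coefficients
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear covariates: some coefficients not estimable",
            call. = FALSE)
  }
  se_col <- if (robust) "robust se" else "se(coef)"
  structure(list(coefficients = co[, "coef"], se = co[, se_col],
                 z = co[, "z"], p = co[, "Pr(>|z|)"], n = s$n,
                 n_events = s$nevent, ties = "breslow", model = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Cox proportional hazards (Breslow ties),", x$n_events, "events /",
      x$n, "subjects\n")
  print(data.frame(coef = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

# Stratified fold assignment: within each class, fold labels are dealt
# round-robin over a random permutation.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Balanced accuracy of binary predictions
#'
#' Mean of the per-class recalls (sensitivity and specificity). Any
#' constant classifier scores exactly 0.5 whenever both classes are
#' present.
#'
#' @param predicted,actual Logical (or 0/1) vectors.
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(predicted, actual) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  stopifnot(length(predicted) == length(actual))
  if (length(unique(actual)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  sens <- mean(predicted[actual])
  spec <- mean(!predicted[!actual])
  (sens + spec) / 2
}

#' L1-regularized logistic relapse prediction with stratified CV
#'
#' Selects the L1 regularization strength by stratified `n_folds`-fold
#' cross-validated binomial deviance (`glmnet`), refits on the training
#' data at the deviance-minimizing strength, and reports coefficients and
#' training balanced accuracy. When every coefficient is shrunk to zero
#' the predictor is the constant majority class and balanced accuracy is
#' exactly 0.5.
#'
#' @param features Numeric matrix or `data.frame` of predictors
#'   (standardized internally by `glmnet`).
#' @param labels Logical or 0/1 outcome with both classes present.
#' @param n_folds Number of CV folds.
#' @param stratified Stratify folds by class?
#' @param seed Optional integer seed for fold assignment.
#' @return A list of class `lasso_cv_result`: `lambda`, `coefficients`
#'   (including intercept), `fold_id`, `balanced_accuracy`,
#'   `all_zero`, and the `cv_fit`.
#' @export
lasso_relapse_cv <- function(features, labels, n_folds = 10,
                             stratified = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(features)
  y <- as.logical(labels)
  if (length(unique(y)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  fold_id <- if (stratified) stratified_folds(y, n_folds) else
    sample(rep_len(seq_len(n_folds), length(y)))
  # glmnet needs >= 2 columns; pad a constant column (never selected)
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, .pad = 0)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          foldid = fold_id, type.measure = "deviance",
                          standardize = TRUE)
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(cf) <- rownames(stats::coef(cv, s = "lambda.min"))
  if (padded) cf <- cf[names(cf) != ".pad"]
  slopes <- cf[-1]
  all_zero <- all(slopes == 0)
  if (all_zero) {
    bacc <- 0.5 # constant majority-class predictor
  } else {
    prob <- as.numeric(stats::predict(cv, newx = x, s = "lambda.min",
                                      type = "response"))
    bacc <- balanced_accuracy(prob > 0.5, y)
  }
  structure(list(lambda = cv$lambda.min, coefficients = cf,
                 fold_id = fold_id, balanced_accuracy = bacc,
                 all_zero = all_zero, cv_fit = cv),
            class = "lasso_cv_result")
}

#' @export
print.lasso_cv_result <- function(x, ...) {
  cat(sprintf("Lasso logistic CV: lambda = %.4g, balanced accuracy = %.3f%s\n",
              x$lambda, x$balanced_accuracy,
              if (x$all_zero) " (all coefficients zero)" else ""))
  invisible(x)
}

# Fit an lmer model with a per-participant random slope, falling back to
# random intercepts when the slope model fails or is singular.
fit_lme_with_fallback <- function(formula_slope, formula_intercept, data) {
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(formula_slope, data = data,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore"))),
    error = function(e) NULL, warning = function(w) NULL)
  fallback <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
  if (fallback) {
    fit <- suppressMessages(lmerTest::lmer(formula_intercept, data = data))
  }
  co <- stats::coef(summary(fit))
  list(fixed = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                          se = co[, "Std. Error"], df = co[, "df"],
                          t = co[, "t value"], p = co[, "Pr(>|t|)"],
                          row.names = NULL),
       varcorr = lme4::VarCorr(fit),
       random_effects = if (fallback) "intercept_only" else
         "intercept_and_slope",
       model = fit)
}

#' Mixed-effects model of discounting across discontinuation
#'
#' Fits `log_k ~ arm * timepoint` with per-participant random effects:
#' a random slope over timepoint where identifiable, else a documented
#' fallback to random intercepts (flagged in `random_effects`). The
#' `arm:timepoint` interaction estimates the effect of discontinuation on
#' the change in log K.
#'
#' @param data `data.frame` with columns `participant_id`, `arm`
#'   (`"MA1-D-MA2"`/`"MA1-MA2-D"`), `timepoint` (`"MA1"`/`"MA2"`), and
#'   `log_k`; two timepoints per included participant.
#' @return A list of class `lme_result`: `fixed` (term, estimate, se, df,
#'   t, p), `varcorr`, `random_effects`, `formula`, `model`.
#' @export
lme_discontinuation <- function(data) {
  stopifnot(all(c("participant_id", "arm", "timepoint", "log_k") %in%
                  names(data)))
  data <- data[!is.na(data$log_k), ]
  if (!any(data$timepoint == "MA2")) {
    stop("no MA2 observations: two timepoints are required", call. = FALSE)
  }
  data$time <- as.integer(data$timepoint == "MA2")
  res <- fit_lme_with_fallback(
    log_k ~ arm * time + (1 + time | participant_id),
    log_k ~ arm * time + (1 | participant_id), data)
  res$formula <- "log_k ~ arm * timepoint + (timepoint | participant)"
  class(res) <- "lme_result"
  res
}

#' Mixed-effects model of symptom change against baseline discounting
#'
#' Fits `hamd ~ log_k_ma1 * timepoint + arm * timepoint` with
#' per-participant random effects (random slope over timepoint with a
#' flagged fallback to random intercepts). The `log_k_ma1:timepoint`
#' interaction expresses how symptom change over time depends on baseline
#' discounting; `arm:timepoint` controls for the discontinuation arms.
#'
#' @param data `data.frame` with columns `participant_id`, `arm`,
#'   `timepoint`, `hamd`, `log_k_ma1`.
#' @return A list of class `lme_result` (see [lme_discontinuation()]).
#' @export
lme_symptom_change <- function(data) {
  stopifnot(all(c("participant_id", "arm", "timepoint", "hamd",
                  "log_k_ma1") %in% names(data)))
  data <- data[!is.na(data$hamd), ]
  if (!any(data$timepoint == "MA2")) {
    stop("no MA2 observations: two timepoints are required", call. = FALSE)
  }
  data$time <- as.integer(data$timepoint == "MA2")
  res <- fit_lme_with_fallback(
    hamd ~ log_k_ma1 * time + arm * time + (1 + time | participant_id),
    hamd ~ log_k_ma1 * time + arm * time + (1 | participant_id), data)
  res$formula <-
    "hamd ~ log_k_ma1 * timepoint + arm * timepoint + (timepoint | participant)"
  class(res) <- "lme_result"
  res
}

#' @export
print.lme_result <- function(x, ...) {
  cat("Linear mixed-effects model:", x$formula, "\n")
  cat("Random effects:", x$random_effects, "\n")
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Post-hoc power of a two-sample t-test
#'
#' Exact power via the noncentral t distribution with
#' `df = n1 + n2 - 2` and noncentrality `d * sqrt(n1 * n2 / (n1 + n2))`.
#'
#' @param d Standardized effect size (Cohen's d).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Type-I error rate.
#' @param tails 1 or 2.
#' @return Power in \[0, 1\]; equals `alpha` exactly at `d = 0`
#'   (two-tailed).
#' @examples
#' posthoc_power_t(0.66, 28, 52) # ~0.79
#' @export
posthoc_power_t <- function(d, n1, n2, alpha = 0.05, tails = 2) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Extract per-participant gain scores from a two-timepoint fit
#'
#' The gain score is the jointly estimated change in log K between the
#' two assessments (`delta`), merged with arm and relapse labels for the
#' downstream comparisons (relapsers vs non-relapsers within the
#' discontinue-first arm; discontinue-first vs discontinue-later arm).
#'
#' @param fit A two-timepoint `fit_result` from [em_fit_two_timepoint()].
#' @param cohort Cohort `data.frame` with `participant_id`, `arm`,
#'   `relapsed`, `dropped_out`.
#' @return `data.frame` with columns `participant_id`, `delta`, `arm`,
#'   `relapsed`, `dropped_out`.
#' @export
gain_scores <- function(fit, cohort) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$kind != "two_timepoint" || !"delta" %in% names(fit$estimates)) {
    stop("gain_scores() needs a two-timepoint fit with a delta parameter",
         call. = FALSE)
  }
  merge(fit$estimates[, c("participant_id", "delta")],
        cohort[, c("participant_id", "arm", "relapsed", "dropped_out")],
        by = "participant_id", sort = TRUE)
}
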