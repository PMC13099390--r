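# Participant-level model evaluation: classification accuracy, the
# right-tailed binomial exclusion test, and McFadden's pseudo-R-squared.

#' Right-tailed binomial test of above-chance model accuracy
#'
#' Probability of obtaining `k` or more correct classifications out of
#' `n` by chance: the exact right tail of a Binomial(n, 0.5)
#' distribution. Participants whose choices the fitted model cannot
#' classify better than a coin flip (p > 0.05) are excluded from
#' downstream analyses.
#'
#' @param k Number of correctly classified choices (0 <= k <= n).
#' @param n Number of choices (>= 1).
#' @return The exact right-tail probability; vectorized over `k`/`n`.
#' @examples
#' binomial_exclusion_p(27, 27) # 0.5^27
#' binomial_exclusion_p(19, 27) # ~0.026: smallest k kept at n = 27
#' @export
binomial_exclusion_p <- function(k, n) {
  if (any(n < 1) || any(k < 0)) stop("need n >= 1 and k >= 0", call. = FALSE)
  if (any(k > n)) stop("k cannot exceed n", call. = FALSE)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' McFadden's pseudo-R-squared against the chance model
#'
#' `1 - L_model / L_null`, where `L_model` is the log-likelihood of the
#' observed choices under the fitted parameters and `L_null` assigns
#' every choice probability 0.5 (the same chance standard as the
#' exclusion test). Zero for an uninformative model; approaches 1 as
#' predictions become perfect.
#'
#' @param trials Choice trials `data.frame` (>= 1 row).
#' @param log_k,log_beta Fitted parameters on the log scale.
#' @return Scalar pseudo-R-squared (<= 1).
#' @export
mcfadden_r2 <- function(trials, log_k, log_beta = 0) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("mcfadden_r2() requires at least one trial", call. = FALSE)
  }
  ll_model <- choice_loglik(trials, log_k, log_beta)
  ll_null <- nrow(trials) * log(0.5)
  1 - ll_model / ll_null
}

#' Evaluate model fit for every participant
#'
#' For each participant: classification accuracy (the model's
#' higher-probability option against the observed choice; exact-tie
#' predictions count one half toward accuracy but are scored incorrect
#' for the binomial count, the conservative choice), the right-tailed
#' binomial exclusion p-value on the participant's total concatenated
#' trial count, the exclusion flag (p > 0.05), and McFadden's
#' pseudo-R-squared.
#'
#' @param fit A `fit_result` from [em_fit()], or a `data.frame` with
#'   columns `participant_id`, `log_k_map`, `log_beta_map`.
#' @param choices Canonical choices `data.frame`. Every participant
#'   present must be covered by `fit`.
#' @return A `data.frame` (one row per participant) with columns
#'   `participant_id`, `n_trials`, `n_correct`, `accuracy`, `binom_p`,
#'   `excluded`, `pseudo_r2`; cohort means are attached as attribute
#'   `"summary"`.
#' @export
evaluate_cohort <- function(fit, choices) {
  est <- if (inherits(fit, "fit_result")) fit$estimates else fit
  stopifnot(all(c("participant_id", "log_k_map", "log_beta_map") %in%
                  names(est)))
  by_pp <- split(choices, choices$participant_id)
  missing <- setdiff(names(by_pp), est$participant_id)
  if (length(missing) > 0) {
    stop("participant(s) present in trials but not in fit: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(names(by_pp), function(id) {
    tr <- by_pp[[id]]
    pars <- est[est$participant_id == id, ]
    p_imm <- p_immediate(tr$r_immediate, tr$R_delayed, tr$delay_days,
                         pars$log_k_map[1], pars$log_beta_map[1])
    p_obs <- ifelse(tr$choice == "immediate", p_imm, 1 - p_imm)
    tie <- p_obs == 0.5
    acc_credit <- ifelse(p_obs > 0.5, 1, ifelse(tie, 0.5, 0))
    n <- nrow(tr)
    k <- sum(p_obs > 0.5)          # ties broken toward incorrect
    data.frame(participant_id = id, n_trials = n, n_correct = k,
               accuracy = sum(acc_credit) / n,
               binom_p = binomial_exclusion_p(k, n),
               excluded = binomial_exclusion_p(k, n) > 0.05,
               pseudo_r2 = mcfadden_r2(tr, pars$log_k_map[1],
                                       pars$log_beta_map[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- c(mean_accuracy = mean(out$accuracy),
                            mean_pseudo_r2 = mean(out$pseudo_r2),
                            n_excluded = sum(out$excluded))
  out
}

#' Write per-participant evaluation records
#'
#' @param eval A `data.frame` from [evaluate_cohort()].
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_eval <- function(eval, path) {
  utils::write.csv(eval, path, row.names = FALSE, na = "")
  invisible(path)
}
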