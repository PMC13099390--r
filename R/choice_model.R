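# Hyperbolic subjective value and the softmax (logistic) choice likelihood.

#' Hyperbolic subjective value of a delayed reward
#'
#' The subjective value of a reward `R` available after `d` days under the
#' standard single-parameter hyperbola is `V = R / (1 + K * d)`, where `K`
#' (1/day) is the discount rate. Value equals `R` at `d = 0` and declines
#' hyperbolically with delay; higher `K` means steeper discounting.
#'
#' @param R Delayed reward amount(s), > 0.
#' @param d Delay(s) in days, >= 0.
#' @param K Discount rate(s), > 0 (1/day).
#' @return Numeric vector of subjective values, same units as `R`.
#' @examples
#' subjective_value(75, 20, 0.0065) # ~66.4
#' @export
subjective_value <- function(R, d, K) {
  if (any(!is.finite(R) | R <= 0)) stop("R must be positive", call. = FALSE)
  if (any(!is.finite(d) | d < 0)) stop("d must be >= 0", call. = FALSE)
  if (any(!is.finite(K) | K <= 0)) stop("K must be positive", call. = FALSE)
  R / (1 + K * d)
}

# Softmax argument: beta * (immediate amount - subjective value of delayed).
# Positive values favour the immediate option.
softmax_argument <- function(r_immediate, R_delayed, delay_days,
                             log_k, log_beta) {
  V <- R_delayed / (1 + exp(log_k) * delay_days)
  exp(log_beta) * (r_immediate - V)
}

# Largest double strictly below 1; probabilities are clamped into
# [double.xmin, 1 - eps/2] so no probability is ever exactly 0 or 1.
.p_hi <- 1 - .Machine$double.eps / 2

#' Probability of choosing the immediate reward
#'
#' A logistic sigmoid maps the subjective value difference between the
#' immediate amount and the discounted delayed amount into a choice
#' probability: `p = sigma(beta * (r - V(R, d, K)))` with
#' `sigma(x) = 1 / (1 + exp(-x))`. The inverse temperature
#' `beta = exp(log_beta)` (1/currency) scales choice determinism; the
#' probability is exactly 0.5 at indifference. Computation is numerically
#' stable for extreme arguments, and never returns exactly 0 or 1.
#'
#' @param r_immediate Immediate amount(s).
#' @param R_delayed Delayed amount(s).
#' @param delay_days Delay(s) in days.
#' @param log_k Natural log of the discount rate.
#' @param log_beta Natural log of the inverse temperature (default 0, an
#'   unscaled sigmoid).
#' @return Probability vector in (0, 1).
#' @examples
#' p_immediate(66, 75, 20, log(0.0065)) # ~0.408
#' @export
p_immediate <- function(r_immediate, R_delayed, delay_days, log_k,
                        log_beta = 0) {
  validate_item_geometry(r_immediate, R_delayed, delay_days)
  if (any(!is.finite(log_k)) || any(!is.finite(log_beta))) {
    stop("log_k and log_beta must be finite", call. = FALSE)
  }
  x <- softmax_argument(r_immediate, R_delayed, delay_days, log_k, log_beta)
  p <- stats::plogis(x)
  pmin(pmax(p, .Machine$double.xmin), .p_hi)
}

#' Log-likelihood of observed choices under the hyperbolic-softmax model
#'
#' Sums, over trials, the log probability of the observed choice under
#' given discounting parameters. Computed in log space so that extreme
#' inverse temperatures or discount rates do not underflow.
#'
#' @param trials A `data.frame` with columns `r_immediate`, `R_delayed`,
#'   `delay_days`, `choice` ("immediate"/"delayed"); at least one row.
#' @param log_k,log_beta Parameters on the natural-log scale.
#' @return A scalar log-likelihood (<= 0).
#' @export
choice_loglik <- function(trials, log_k, log_beta = 0) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("choice_loglik() requires at least one trial", call. = FALSE)
  }
  stopifnot(all(trials$choice %in% c("immediate", "delayed")))
  x <- softmax_argument(trials$r_immediate, trials$R_delayed,
                        trials$delay_days, log_k, log_beta)
  imm <- trials$choice == "immediate"
  # log sigma(x) for immediate choices, log sigma(-x) for delayed ones
  sum(stats::plogis(ifelse(imm, x, -x), log.p = TRUE))
}

# Log-likelihood gradient wrt (log_k, log_beta); used by the MAP optimizer.
# d ll / dx = y - sigma(x);  dx/dlog_k = beta*R*d*K/(1+Kd)^2;  dx/dlog_beta = x
choice_loglik_grad <- function(trials, log_k, log_beta = 0) {
  K <- exp(log_k)
  beta <- exp(log_beta)
  denom <- 1 + K * trials$delay_days
  V <- trials$R_delayed / denom
  x <- beta * (trials$r_immediate - V)
  y <- as.numeric(trials$choice == "immediate")
  resid <- y - stats::plogis(x)
  dx_dlogk <- beta * trials$R_delayed * trials$delay_days * K / denom^2
  c(log_k = sum(resid * dx_dlogk), log_beta = sum(resid * x))
}

#' Deterministic choice labels for an item bank
#'
#' Classifies each item of a bank as the choice a noiseless hyperbolic
#' discounter with rate `K` would make: "immediate" when `K` exceeds the
#' item's indifference discount rate, "delayed" when below it, and "tie"
#' at exact equality.
#'
#' @param bank An item bank `data.frame` (see [mcq_item_bank()]).
#' @param K Discount rate, > 0.
#' @return Character vector of labels, one per item.
#' @examples
#' bank <- mcq_item_bank()
#' table(deterministic_choices(bank[bank$magnitude_bin == "small", ], 0.01))
#' @export
deterministic_choices <- function(bank, K) {
  stopifnot(is.finite(K), K > 0)
  k_star <- implied_item_k(bank)
  ifelse(K > k_star, "immediate", ifelse(K < k_star, "delayed", "tie"))
}
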