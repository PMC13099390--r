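# Simulator of the adaptive questionnaire: a MAP-update staircase that
# re-estimates the discount rate after every choice and places the next
# immediate offer at the currently estimated indifference point, stopping
# once the running estimate stabilises.

#' Offer schedule for the adaptive task
#'
#' A fixed schedule of (delayed amount, delay) pairs cycling through three
#' reward magnitudes and five delays; the immediate amount of each trial
#' is constructed at run time from the current discount-rate estimate.
#'
#' @param R_values Delayed reward magnitudes.
#' @param delays Delays in days.
#' @return A `data.frame` with columns `R_delayed`, `delay_days`, one row
#'   per scheduled trial (magnitudes crossed with delays).
#' @export
adaptive_schedule <- function(R_values = c(30, 55, 80),
                              delays = c(7, 20, 50, 90, 160)) {
  stopifnot(all(R_values > 1), all(delays >= 1))
  grid <- expand.grid(R_delayed = R_values, delay_days = delays,
                      KEEP.OUT.ATTRS = FALSE)
  grid[order(grid$delay_days, grid$R_delayed), , drop = FALSE]
}

#' Construct the next adaptive offer at the current indifference point
#'
#' Places the immediate amount at the subjective value the current
#' discount-rate estimate assigns to the scheduled delayed reward,
#' rounded to a whole currency unit and clipped into `[1, R - 1]`, so the
#' implied indifference rate of the offer equals the running estimate up
#' to rounding.
#'
#' @param R_delayed Scheduled delayed amount (> 1).
#' @param delay_days Scheduled delay in days.
#' @param current_log_k Current estimate of log K.
#' @return Named numeric vector `(r_immediate, R_delayed, delay_days)`.
#' @examples
#' next_offer(75, 20, log(0.0065)) # immediate offer 66
#' @export
next_offer <- function(R_delayed, delay_days, current_log_k) {
  if (!is.finite(R_delayed) || R_delayed <= 1) {
    stop("degenerate schedule: R_delayed must exceed 1", call. = FALSE)
  }
  stopifnot(is.finite(current_log_k), delay_days >= 1)
  r <- round(subjective_value(R_delayed, delay_days, exp(current_log_k)))
  r <- min(max(r, 1), R_delayed - 1)
  c(r_immediate = r, R_delayed = R_delayed, delay_days = delay_days)
}

#' Update the running discount-rate estimate from choice history
#'
#' MAP estimate of `log_k` given all choices so far, under the session
#' prior with the inverse temperature pinned (the staircase estimates a
#' single parameter). Deterministic given the history: optimization
#' starts from the prior mean and the previous estimate only, with no
#' random restarts.
#'
#' @param history A `data.frame` of past trials (canonical choice
#'   columns), >= 1 row.
#' @param prior A [prior_hyper()] over `log_k` (a `log_beta` coordinate,
#'   if present, is dropped and its mean used as the pinned value).
#' @param previous Optional previous estimate used as a warm start.
#' @return The MAP `log_k` (scalar).
#' @export
update_estimate <- function(history, prior, previous = NULL) {
  pinned_lb <- if ("log_beta" %in% names(prior$mean)) {
    unname(prior$mean["log_beta"])
  } else 0
  pk <- prior_hyper(prior$mean["log_k"],
                    prior$cov["log_k", "log_k", drop = FALSE])
  init <- if (is.null(previous)) NULL else c(log_k = previous)
  fit <- map_fit(history, pk, init = init, n_restarts = 0,
                 pinned_log_beta = pinned_lb)
  unname(fit$par["log_k"])
}

#' Softmax choice agent
#'
#' Returns a function `(r, R, d) -> "immediate"/"delayed"` sampling from
#' the hyperbolic-softmax model at fixed parameters, consuming the
#' current RNG stream.
#'
#' @param log_k,log_beta Agent parameters (natural-log scale).
#' @return A choice-generating function.
#' @export
softmax_agent <- function(log_k, log_beta = 0) {
  force(log_k); force(log_beta)
  function(r_immediate, R_delayed, delay_days) {
    p <- p_immediate(r_immediate, R_delayed, delay_days, log_k, log_beta)
    if (stats::runif(1) < p) "immediate" else "delayed"
  }
}

#' Noiseless choice agent
#'
#' Returns a deterministic agent choosing whichever option has the higher
#' subjective value at discount rate `exp(log_k)`; exact ties go to the
#' delayed option.
#'
#' @param log_k Agent discount rate on the log scale.
#' @return A choice-generating function.
#' @export
deterministic_agent <- function(log_k) {
  force(log_k)
  function(r_immediate, R_delayed, delay_days) {
    V <- subjective_value(R_delayed, delay_days, exp(log_k))
    if (r_immediate > V) "immediate" else "delayed"
  }
}

#' Run one adaptive session
#'
#' Simulates the adaptive questionnaire against a choice-generating
#' agent: each trial's immediate offer is placed at the indifference
#' point of the running MAP estimate, the agent chooses, and the estimate
#' is updated. The session stops once the running `log_k` estimate has
#' varied by less than `tol` over the last `window` trials (`stable`), or
#' at `max_trials`.
#'
#' @param agent A function `(r, R, d) -> "immediate"/"delayed"`, e.g.
#'   [softmax_agent()].
#' @param prior Session prior over `log_k` (and optionally a pinned
#'   `log_beta` mean); defaults to mean (-4, 0), covariance `2 * I`.
#' @param schedule Offer schedule, recycled as needed (see
#'   [adaptive_schedule()]).
#' @param window,tol Stability window (trials) and tolerance on the
#'   running `log_k`.
#' @param max_trials Session cap.
#' @param seed Optional integer seed for reproducible stochastic agents.
#' @param participant_id,timepoint Labels written into the trial log.
#' @return An object of class `adaptive_session`: `trials` (canonical
#'   choices rows with `task_tag = "adaptive"`), `running_log_k`,
#'   `final_log_k`, `stopped_reason` ("stable" or "max_trials").
#' @export
run_session <- function(agent,
                        prior = prior_hyper(c(log_k = -4, log_beta = 0),
                                            diag(2, 2)),
                        schedule = adaptive_schedule(),
                        window = 3, tol = 0.05, max_trials = 30,
                        seed = NULL, participant_id = "sim",
                        timepoint = "MA1") {
  if (!is.null(seed)) set.seed(seed)
  est <- unname(prior$mean["log_k"])
  running <- numeric(0)
  rows <- vector("list", max_trials)
  stopped_reason <- "max_trials"
  n_done <- 0
  for (t in seq_len(max_trials)) {
    sched <- schedule[(t - 1) %% nrow(schedule) + 1, ]
    offer <- next_offer(sched$R_delayed, sched$delay_days, est)
    choice <- agent(offer["r_immediate"], offer["R_delayed"],
                    offer["delay_days"])
    rows[[t]] <- data.frame(
      participant_id = participant_id, timepoint = timepoint,
      task_tag = "adaptive", trial_index = t,
      r_immediate = unname(offer["r_immediate"]),
      R_delayed = unname(offer["R_delayed"]),
      delay_days = unname(offer["delay_days"]),
      choice = choice, stringsAsFactors = FALSE)
    history <- do.call(rbind, rows[seq_len(t)])
    est <- update_estimate(history, prior, previous = est)
    running <- c(running, est)
    n_done <- t
    if (t > window &&
        diff(range(running[(t - window):t])) < tol) {
      stopped_reason <- "stable"
      break
    }
  }
  structure(list(trials = do.call(rbind, rows[seq_len(n_done)]),
                 running_log_k = running, final_log_k = est,
                 stopped_reason = stopped_reason),
            class = "adaptive_session")
}

#' @export
print.adaptive_session <- function(x, ...) {
  cat("Adaptive session:", nrow(x$trials), "trials, stopped on",
      x$stopped_reason, "\n  final log K:", round(x$final_log_k, 3),
      "(K =", signif(exp(x$final_log_k), 3), "/day)\n")
  invisible(x)
}
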