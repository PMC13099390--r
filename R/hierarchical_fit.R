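# Empirical-Bayes hierarchical fitting: per-participant MAP estimates under
# a population Gaussian prior whose hyperparameters are learned by EM, with
# Laplace posterior covariances. Supports the joint two-timepoint
# (log_k at MA1, delta) parameterization used for gain scores.

#' Construct a population prior over discounting parameters
#'
#' @param mean Named numeric vector of prior means on the fitting scale.
#' @param cov Symmetric positive-definite covariance matrix over the same
#'   coordinates.
#' @return An object of class `prior_hyper`.
#' @export
prior_hyper <- function(mean, cov) {
  stopifnot(is.numeric(mean), !is.null(names(mean)), all(is.finite(mean)))
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  if (max(abs(cov - t(cov))) > 1e-8) stop("prior covariance must be symmetric")
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("prior covariance must be positive definite")
  }
  dimnames(cov) <- list(names(mean), names(mean))
  structure(list(mean = mean, cov = cov), class = "prior_hyper")
}

# Multivariate normal log density and gradient at a single point.
dmvn_log <- function(theta, prior) {
  p <- length(prior$mean)
  ch <- chol(prior$cov)
  z <- backsolve(ch, theta - prior$mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

dmvn_grad <- function(theta, prior) {
  -solve(prior$cov, theta - prior$mean)
}

#' Fitting configuration
#'
#' Bundles the tunable knobs of the EM fitting procedure. The prior is
#' initialized at mean (-4, 0[, 0]) on (log_k, log_beta[, delta]) with
#' covariance 2*I; exp(-4) ~ 0.018/day sits mid-range of the MCQ item
#' indifference rates.
#'
#' @param seed Integer seed; required. All stochastic restarts flow from
#'   one generator seeded here.
#' @param max_em_iter Maximum EM iterations.
#' @param em_tol Convergence tolerance: maximum absolute change in any
#'   hyperparameter (prior mean or covariance entry) between iterations.
#' @param n_restarts Number of random optimizer restarts drawn from the
#'   current prior (first E-step; later iterations warm-start from the
#'   previous MAP).
#' @param pin_log_beta If `TRUE`, the inverse temperature is fixed at
#'   `pinned_log_beta` rather than fitted.
#' @param pinned_log_beta Value at which `log_beta` is pinned.
#' @param pin_delta Two-timepoint fits only: fix the change parameter at 0
#'   (used for reparameterization checks).
#' @param covariance_mode `"full"` or `"diagonal"` prior covariance.
#' @param cov_floor Eigenvalue floor for the prior covariance.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(seed, max_em_iter = 100, em_tol = 1e-3,
                       n_restarts = 5, pin_log_beta = FALSE,
                       pinned_log_beta = 0, pin_delta = FALSE,
                       covariance_mode = c("full", "diagonal"),
                       cov_floor = 1e-4) {
  if (missing(seed) || !is.finite(seed)) stop("seed is required", call. = FALSE)
  structure(list(seed = as.integer(seed), max_em_iter = max_em_iter,
                 em_tol = em_tol, n_restarts = n_restarts,
                 pin_log_beta = pin_log_beta,
                 pinned_log_beta = pinned_log_beta, pin_delta = pin_delta,
                 covariance_mode = match.arg(covariance_mode),
                 cov_floor = cov_floor),
            class = "fit_config")
}

#' Read a fitting configuration from a flat YAML file
#'
#' @param path Path to a YAML file of `key: value` pairs matching the
#'   arguments of [fit_config()].
#' @return A `fit_config` object.
#' @export
read_fit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(fit_config, vals)
}

# Build fast log-likelihood/gradient closures over a named parameter vector.
# mode "single": theta holds log_k (+ log_beta unless pinned); all trials
# share parameters. mode "two": theta holds log_k_ma1 (+ delta unless
# pinned, + log_beta unless pinned); MA2 trials use log_k_ma1 + delta.
make_objective <- function(trials, mode = c("single", "two"),
                           pin_log_beta = FALSE, pinned_log_beta = 0,
                           pin_delta = FALSE) {
  mode <- match.arg(mode)
  grab <- function(tr) list(r = tr$r_immediate, R = tr$R_delayed,
                            d = tr$delay_days,
                            y = as.numeric(tr$choice == "immediate"))
  ll_part <- function(dat, log_k, log_beta) {
    denom <- 1 + exp(log_k) * dat$d
    x <- exp(log_beta) * (dat$r - dat$R / denom)
    sum(stats::plogis(ifelse(dat$y == 1, x, -x), log.p = TRUE))
  }
  grad_part <- function(dat, log_k, log_beta) {
    K <- exp(log_k)
    denom <- 1 + K * dat$d
    x <- exp(log_beta) * (dat$r - dat$R / denom)
    resid <- dat$y - stats::plogis(x)
    dx_dlogk <- exp(log_beta) * dat$R * dat$d * K / denom^2
    c(lk = sum(resid * dx_dlogk), lb = sum(resid * x))
  }
  if (mode == "single") {
    dat <- grab(trials)
    par_names <- "log_k"
    if (!pin_log_beta) par_names <- c(par_names, "log_beta")
    fn <- function(theta) {
      lb <- if (pin_log_beta) pinned_log_beta else theta[["log_beta"]]
      ll_part(dat, theta[["log_k"]], lb)
    }
    gr <- function(theta) {
      lb <- if (pin_log_beta) pinned_log_beta else theta[["log_beta"]]
      g <- grad_part(dat, theta[["log_k"]], lb)
      out <- c(log_k = unname(g["lk"]))
      if (!pin_log_beta) out <- c(out, log_beta = unname(g["lb"]))
      out
    }
  } else {
    stopifnot("timepoint" %in% names(trials))
    dat1 <- grab(trials[trials$timepoint == "MA1", , drop = FALSE])
    dat2 <- grab(trials[trials$timepoint == "MA2", , drop = FALSE])
    par_names <- "log_k_ma1"
    if (!pin_delta) par_names <- c(par_names, "delta")
    if (!pin_log_beta) par_names <- c(par_names, "log_beta")
    fn <- function(theta) {
      lb <- if (pin_log_beta) pinned_log_beta else theta[["log_beta"]]
      dl <- if (pin_delta) 0 else theta[["delta"]]
      ll_part(dat1, theta[["log_k_ma1"]], lb) +
        ll_part(dat2, theta[["log_k_ma1"]] + dl, lb)
    }
    gr <- function(theta) {
      lb <- if (pin_log_beta) pinned_log_beta else theta[["log_beta"]]
      dl <- if (pin_delta) 0 else theta[["delta"]]
      g1 <- grad_part(dat1, theta[["log_k_ma1"]], lb)
      g2 <- grad_part(dat2, theta[["log_k_ma1"]] + dl, lb)
      out <- c(log_k_ma1 = unname(g1["lk"] + g2["lk"]))
      if (!pin_delta) out <- c(out, delta = unname(g2["lk"]))
      if (!pin_log_beta) out <- c(out, log_beta = unname(g1["lb"] + g2["lb"]))
      out
    }
  }
  list(fn = fn, gr = gr, par_names = par_names)
}

#' Maximum-a-posteriori fit for one participant
#'
#' Maximizes log-likelihood plus Gaussian log prior density over the
#' parameters named in `prior$mean`, by quasi-Newton (BFGS) optimization
#' with analytic gradients from multiple starts: the supplied `init`, the
#' prior mean, and `n_restarts` random draws from the prior (consuming the
#' current RNG stream). The best penalized objective wins, ties broken by
#' first found. Laplace posterior variances are the diagonal of the
#' inverse Hessian of the negative penalized objective at the MAP; the
#' Hessian is ridge-regularized if numerically non-positive-definite (the
#' result is then flagged).
#'
#' @param trials One participant's choice trials (>= 1 row). For
#'   two-timepoint priors (parameter `log_k_ma1`/`delta`) the `timepoint`
#'   column selects which discount rate each trial uses.
#' @param prior A [prior_hyper()] whose names define the fitted parameters
#'   (`log_k`, optionally `log_beta`; or `log_k_ma1`, `delta`,
#'   `log_beta`).
#' @param init Optional named start vector.
#' @param n_restarts Number of random restarts drawn from the prior.
#' @param pinned_log_beta Value of `log_beta` when it is not a fitted
#'   coordinate of the prior.
#' @return A list with elements `par` (named MAP vector), `laplace_cov`,
#'   `laplace_var` (its diagonal), `loglik` (data log-likelihood at the
#'   MAP), `penalized` (penalized objective), `converged`, and `flags`.
#' @export
map_fit <- function(trials, prior, init = NULL, n_restarts = 5,
                    pinned_log_beta = 0) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("map_fit() requires at least one trial", call. = FALSE)
  }
  nm <- names(prior$mean)
  mode <- if ("log_k_ma1" %in% nm) "two" else "single"
  obj <- make_objective(trials, mode = mode,
                        pin_log_beta = !("log_beta" %in% nm),
                        pinned_log_beta = pinned_log_beta,
                        pin_delta = mode == "two" && !("delta" %in% nm))
  if (!setequal(obj$par_names, nm)) {
    stop("prior parameters do not match objective: ",
         paste(nm, collapse = ","), call. = FALSE)
  }
  neg_fn <- function(th) { names(th) <- nm; -(obj$fn(th) + dmvn_log(th, prior)) }
  neg_gr <- function(th) { names(th) <- nm; -(obj$gr(th)[nm] + dmvn_grad(th, prior)) }

  starts <- list(prior$mean)
  if (!is.null(init)) starts <- c(list(init[nm]), starts)
  if (n_restarts > 0) {
    L <- chol(prior$cov)
    for (i in seq_len(n_restarts)) {
      z <- stats::rnorm(length(nm))
      starts <- c(starts, list(prior$mean + drop(t(L) %*% z)))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, neg_fn, neg_gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("map_fit(): optimization failed from every start",
                          call. = FALSE)
  flags <- character(0)
  if (best$convergence != 0) flags <- c(flags, "optim_nonzero_convergence")
  H <- tryCatch(stats::optimHess(best$par, neg_fn, neg_gr),
                error = function(e) NULL)
  lap <- NULL
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    ridge <- 0
    repeat {
      ev <- eigen(H + diag(ridge, nrow(H)), symmetric = TRUE,
                  only.values = TRUE)$values
      if (min(ev) > 1e-10) break
      ridge <- if (ridge == 0) 1e-8 else ridge * 10
      if (ridge > 1e2) break
    }
    if (ridge > 0) flags <- c(flags, "hessian_regularized")
    lap <- tryCatch(solve(H + diag(ridge, nrow(H))), error = function(e) NULL)
  }
  if (is.null(lap)) {
    flags <- c(flags, "laplace_unavailable")
    lap <- diag(NA_real_, length(nm))
  }
  dimnames(lap) <- list(nm, nm)
  par <- best$par
  names(par) <- nm
  list(par = par, laplace_cov = lap, laplace_var = diag(lap),
       loglik = obj$fn(par), penalized = -best$value,
       converged = best$convergence == 0 && !("laplace_unavailable" %in% flags),
       flags = flags)
}

# Floor eigenvalues of a covariance matrix; returns list(cov, floored).
floor_covariance <- function(S, floor) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floored <- any(e$values < floor)
  vals <- pmax(e$values, floor)
  list(cov = e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors),
       floored = floored)
}

# Shared EM engine over a list of per-participant trial data frames.
em_engine <- function(trials_list, par_names, mode, config) {
  n <- length(trials_list)
  if (n < 2) stop("EM fitting requires at least 2 participants", call. = FALSE)
  p <- length(par_names)
  mu <- stats::setNames(rep(0, p), par_names)
  mu[grep("^log_k", par_names)] <- -4
  prior <- prior_hyper(mu, diag(2, p))

  set.seed(config$seed)
  theta <- matrix(NA_real_, n, p, dimnames = list(names(trials_list), par_names))
  laps <- vector("list", n)
  warm <- vector("list", n)
  objective_trace <- numeric(0)
  loglik_i <- numeric(n)
  conv_i <- logical(n)
  floored_any <- FALSE
  converged <- FALSE
  iter <- 0

  while (iter < config$max_em_iter) {
    iter <- iter + 1
    pen_sum <- 0
    for (i in seq_len(n)) {
      res <- map_fit(trials_list[[i]], prior, init = warm[[i]],
                     n_restarts = if (iter == 1) config$n_restarts else 0,
                     pinned_log_beta = config$pinned_log_beta)
      theta[i, ] <- res$par
      laps[[i]] <- res$laplace_cov
      warm[[i]] <- res$par
      loglik_i[i] <- res$loglik
      conv_i[i] <- res$converged
      pen_sum <- pen_sum + res$penalized
    }
    objective_trace <- c(objective_trace, pen_sum)

    mu_new <- colMeans(theta)
    centred <- sweep(theta, 2, mu_new)
    S <- crossprod(centred) / n
    lap_ok <- Filter(function(L) all(is.finite(L)), laps)
    if (length(lap_ok) > 0) {
      S <- S + Reduce(`+`, lap_ok) / n
    }
    if (config$covariance_mode == "diagonal") S <- diag(diag(S), p)
    fl <- floor_covariance(S, config$cov_floor)
    if (fl$floored) floored_any <- TRUE
    S <- fl$cov
    dimnames(S) <- list(par_names, par_names)

    delta_h <- max(abs(mu_new - prior$mean), abs(S - prior$cov))
    prior <- prior_hyper(mu_new, S)
    if (delta_h < config$em_tol) { converged <- TRUE; break }
  }
  if (floored_any) {
    warning("prior covariance eigenvalues floored at ", config$cov_floor,
            call. = FALSE)
  }
  list(theta = theta, laps = laps, prior = prior, n_iter = iter,
       converged = converged, objective_trace = objective_trace,
       loglik = loglik_i, conv_i = conv_i)
}

#' Hierarchical empirical-Bayes fit of discounting parameters
#'
#' Alternates (E) per-participant MAP fits with Laplace posterior
#' covariances under the current population prior with (M) hyperparameter
#' updates -- prior mean set to the average MAP, prior covariance to the
#' average of centred-MAP outer products plus Laplace covariances -- until
#' the hyperparameters change by less than `em_tol` or `max_em_iter` is
#' reached. The empirical prior regularises weakly-constrained
#' participants (e.g. all-immediate responders) toward the population
#' mean. Fitting uses each participant's trials as given; pass the
#' concatenated MCQ + adaptive trials per participant.
#'
#' @param choices A choices `data.frame` in the canonical schema (one row
#'   per trial; >= 2 distinct participants).
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `estimates` (one row per
#'   participant: MAP parameters, Laplace variances, log-likelihood,
#'   convergence flag), `prior` (final [prior_hyper()]), `n_iter`,
#'   `converged`, `objective_trace` (summed penalized objective at each
#'   E-step), `laplace` (per-participant covariance list), and `config`.
#' @export
em_fit <- function(choices, config) {
  stopifnot(inherits(config, "fit_config"))
  trials_list <- split(choices, choices$participant_id)
  par_names <- "log_k"
  if (!config$pin_log_beta) par_names <- c(par_names, "log_beta")
  eng <- em_engine(trials_list, par_names, "single", config)
  est <- data.frame(
    participant_id = rownames(eng$theta),
    log_k_map = eng$theta[, "log_k"],
    log_beta_map = if (config$pin_log_beta) config$pinned_log_beta
                   else eng$theta[, "log_beta"],
    laplace_var_log_k = vapply(eng$laps, function(L) L["log_k", "log_k"],
                               numeric(1)),
    laplace_var_log_beta = if (config$pin_log_beta) NA_real_ else
      vapply(eng$laps, function(L) L["log_beta", "log_beta"], numeric(1)),
    loglik = eng$loglik,
    converged = eng$conv_i,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(estimates = est, prior = eng$prior, n_iter = eng$n_iter,
                 converged = eng$converged,
                 objective_trace = eng$objective_trace,
                 laplace = eng$laps, config = config, kind = "single"),
            class = "fit_result")
}

#' Joint two-timepoint hierarchical fit (baseline and change)
#'
#' Fits each participant's MA1 and MA2 trials jointly under the
#' parameterization (`log_k_ma1`, `delta`): MA1 trials use
#' `exp(log_k_ma1)`, MA2 trials use `exp(log_k_ma1 + delta)`. Estimating
#' the change parameter concurrently with baseline avoids the error
#' accumulation of differencing two independently fitted noisy estimates;
#' the fitted `delta` is the gain score used downstream. The hierarchical
#' prior spans all fitted coordinates; the inverse temperature is shared
#' across timepoints (or pinned via the config).
#'
#' @param choices Canonical choices `data.frame` containing both
#'   timepoints. Participants missing a timepoint are excluded with a
#'   message.
#' @param config A [fit_config()]; set `pin_delta = TRUE` to pin the
#'   change parameter at 0 (reparameterization checks).
#' @return A `fit_result` whose `estimates` carry `log_k_ma1`, `delta`,
#'   `log_beta_map`, Laplace variances, and per-participant convergence.
#' @export
em_fit_two_timepoint <- function(choices, config) {
  stopifnot(inherits(config, "fit_config"))
  trials_list <- split(choices, choices$participant_id)
  has_both <- vapply(trials_list, function(tr) {
    all(c("MA1", "MA2") %in% tr$timepoint)
  }, logical(1))
  if (any(!has_both)) {
    message(sum(!has_both), " participant(s) missing a timepoint excluded ",
            "from the two-timepoint fit: ",
            paste(names(trials_list)[!has_both], collapse = ", "))
  }
  trials_list <- trials_list[has_both]
  par_names <- "log_k_ma1"
  if (!config$pin_delta) par_names <- c(par_names, "delta")
  if (!config$pin_log_beta) par_names <- c(par_names, "log_beta")
  eng <- em_engine(trials_list, par_names, "two", config)
  est <- data.frame(
    participant_id = rownames(eng$theta),
    log_k_ma1 = eng$theta[, "log_k_ma1"],
    delta = if (config$pin_delta) 0 else eng$theta[, "delta"],
    log_beta_map = if (config$pin_log_beta) config$pinned_log_beta
                   else eng$theta[, "log_beta"],
    laplace_var_log_k = vapply(eng$laps, function(L)
      L["log_k_ma1", "log_k_ma1"], numeric(1)),
    laplace_var_delta = if (config$pin_delta) NA_real_ else
      vapply(eng$laps, function(L) L["delta", "delta"], numeric(1)),
    loglik = eng$loglik,
    converged = eng$conv_i,
    row.names = NULL, stringsAsFactors = FALSE
  )
  est$log_k_ma2 <- est$log_k_ma1 + est$delta
  structure(list(estimates = est, prior = eng$prior, n_iter = eng$n_iter,
                 converged = eng$converged,
                 objective_trace = eng$objective_trace,
                 laplace = eng$laps, config = config, kind = "two_timepoint"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Hierarchical", if (x$kind == "two_timepoint") "two-timepoint" else
      "single-timepoint", "empirical-Bayes fit\n")
  cat("  participants:", nrow(x$estimates), "\n")
  cat("  EM iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  prior mean:", paste(sprintf("%s=%.3f", names(x$prior$mean),
                                     x$prior$mean), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize fit estimates to a delimited file
#'
#' @param fit A `fit_result`.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  utils::write.csv(fit$estimates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read serialized fit estimates
#'
#' @param path CSV path written by [write_fit()].
#' @return A `data.frame` of per-participant estimates.
#' @export
read_fit <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}
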