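# Shared fixtures: simulated choice sets and an exact big-integer
# binomial-tail oracle.

# Simulate softmax choices on the MCQ bank (repeated n_rep times).
sim_mcq_trials <- function(log_k, log_beta = 0, n_rep = 1, seed = 1,
                           id = "x", timepoint = "MA1") {
  set.seed(seed)
  bank <- mcq_item_bank()
  tr <- bank[rep(seq_len(nrow(bank)), n_rep), ]
  p <- p_immediate(tr$r_immediate, tr$R_delayed, tr$delay_days,
                   log_k, log_beta)
  data.frame(participant_id = id, timepoint = timepoint, task_tag = "mcq",
             trial_index = seq_len(nrow(tr)),
             r_immediate = tr$r_immediate, R_delayed = tr$R_delayed,
             delay_days = tr$delay_days,
             choice = ifelse(stats::runif(nrow(tr)) < p,
                             "immediate", "delayed"),
             stringsAsFactors = FALSE)
}

# Simulate a small multi-participant choice set at given latent log_k.
sim_group_trials <- function(log_k_vec, log_beta = log(2), n_rep = 2,
                             seed = 1) {
  do.call(rbind, lapply(seq_along(log_k_vec), function(i) {
    sim_mcq_trials(log_k_vec[i], log_beta, n_rep = n_rep,
                   seed = seed * 1000 + i, id = sprintf("P%03d", i))
  }))
}

# --- exact big-integer arithmetic (base 1e7 limbs, little-endian) -------

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e7
    s[i] <- s[i] %% 1e7
  }
  while (carry > 0) {
    s <- c(s, carry %% 1e7)
    carry <- carry %/% 1e7
  }
  s
}

big_to_double <- function(a) sum(a * 1e7^(seq_along(a) - 1))

# Exact right-tail Binomial(n, 1/2) probabilities for all k = 0..n, via
# Pascal's triangle in big integers; returned as doubles (the only
# rounding is the final conversion).
oracle_binom_tail <- function(n) {
  row <- list(c(1))
  for (m in seq_len(n)) {
    new_row <- vector("list", m + 1)
    new_row[[1]] <- c(1)
    new_row[[m + 1]] <- c(1)
    if (m > 1) {
      for (j in 2:m) new_row[[j]] <- big_add(row[[j - 1]], row[[j]])
    }
    row <- new_row
  }
  tails <- vector("list", n + 1)
  tails[[n + 1]] <- row[[n + 1]]
  for (k in n:1) tails[[k]] <- big_add(tails[[k + 1]], row[[k]])
  vapply(tails, big_to_double, numeric(1)) / 2^n
}
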