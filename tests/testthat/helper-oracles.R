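# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# Habit value by the direct kernel sum H_i(t) = sum_s exp(-s/kappa) c_i(t-s)
oracle_habit_direct <- function(options, kappa, option_set) {
  idx <- match(options, option_set)
  N <- length(idx)
  K <- length(option_set)
  H <- matrix(0, N, K)
  for (t in seq_len(N)) {
    if (t == 1L) next
    s <- (t - 1):1
    past <- idx[seq_len(t - 1L)]
    w <- exp(-(t - seq_len(t - 1L)) / kappa)
    for (i in seq_len(K)) H[t, i] <- sum(w[past == i])
  }
  H
}

# Independent re-implementation of the dual-control forward pass in
# plain R, from the model equations.
oracle_dc_nll <- function(choice_idx, rewards, alpha_c, alpha_u, kappa,
                          beta_G, beta_H, use_goal, use_habit,
                          decay_unchosen) {
  K <- length(rewards)
  Q <- numeric(K); H <- numeric(K)
  d <- exp(-1 / kappa)
  nll <- 0
  for (t in seq_along(choice_idx)) {
    c <- choice_idx[t]
    z <- (if (use_goal) beta_G * Q else 0) +
         (if (use_habit) beta_H * H else 0)
    if (length(z) == 1L) z <- rep(z, K)
    p <- exp(z - max(z)); p <- p / sum(p)
    nll <- nll - log(p[c])
    if (use_goal) {
      Q[c] <- Q[c] + alpha_c * (rewards[c] - Q[c])
      if (decay_unchosen) {
        u <- setdiff(seq_len(K), c)
        Q[u] <- Q[u] + alpha_u * (0 - Q[u])
      }
    }
    if (use_habit) {
      ct <- numeric(K); ct[c] <- 1
      H <- d * (H + ct)
    }
  }
  nll
}

# Survival/hazard of run lengths by explicit counting.
oracle_run_survival <- function(lengths, l) mean(lengths >= l)

# Simulate an inhomogeneous Poisson record with a sinusoidal daily rate,
# by thinning (used as a known-period oracle for the autocorrelogram).
oracle_sinusoid_log <- function(period_hours, days, rate0 = 0.02,
                                seed = 1) {
  set.seed(seed)
  lam_max <- 2 * rate0
  tt <- numeric(0)
  t <- 0
  dur <- days * 86400
  while (TRUE) {
    t <- t + stats::rexp(1, lam_max)
    if (t >= dur) break
    lam <- rate0 * (1 + cos(2 * pi * t / (period_hours * 3600)))
    if (stats::runif(1) < lam / lam_max) tt <- c(tt, t)
  }
  event_log(tt, rep("X", length(tt)), duration = dur)
}

# A strongly persistent 4-option sequence: repeat the previous choice
# with probability p_repeat, otherwise draw uniformly.
persistent_sequence <- function(n, p_repeat = 0.9, seed = 1,
                                options = LETTERS[1:4]) {
  set.seed(seed)
  out <- character(n)
  out[1] <- sample(options, 1)
  for (t in 2:n) {
    out[t] <- if (stats::runif(1) < p_repeat) out[t - 1]
              else sample(options, 1)
  }
  out
}
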