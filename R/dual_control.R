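#' @useDynLib foragedyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Variant table: which parameters are free and which systems are active.
# k (free-parameter count) is the length of `free`.
.dc_variants <- list(
  dual         = list(free = c("alpha_c", "alpha_u", "a", "kappa",
                               "beta_G", "beta_H"),
                      goal = TRUE, habit = TRUE, decay = TRUE),
  goal_cu      = list(free = c("alpha_c", "alpha_u", "a", "beta_G"),
                      goal = TRUE, habit = FALSE, decay = TRUE),
  goal_c       = list(free = c("alpha_c", "a", "beta_G"),
                      goal = TRUE, habit = FALSE, decay = FALSE),
  habit        = list(free = c("kappa", "beta_H"),
                      goal = FALSE, habit = TRUE, decay = FALSE),
  goal_c_habit = list(free = c("alpha_c", "a", "kappa", "beta_G",
                               "beta_H"),
                      goal = TRUE, habit = TRUE, decay = FALSE))

#' Dual-control choice model parameters
#'
#' The dual-control model combines two valuation systems evaluated in
#' parallel on every trial: a *goal-directed* system holding reward
#' values `Q` updated by temporal-difference prediction errors (chosen
#' option learns at rate `alpha_c`; unchosen options decay toward zero at
#' rate `alpha_u`), and a *habit* system holding leaky-integrated choice
#' history `H` with decay constant `kappa` trials. Choice probability is
#' softmax over `beta_G * Q + beta_H * H`. Reward values derive from mean
#' choice rates through the generalized matching law with sensitivity
#' `a` (see [reward_values()]).
#'
#' Nested variants switch systems off: `goal_cu` (no habit), `goal_c`
#' (no habit, no unchosen decay), `habit` (no goal system),
#' `goal_c_habit` (both, no unchosen decay). Free-parameter counts are
#' 6, 4, 3, 2, 5 respectively.
#'
#' @param alpha_c Chosen-option learning rate, in `[0, 1]`.
#' @param alpha_u Unchosen-option decay rate, in `[0, 1]`.
#' @param kappa Habit decay constant, trials (> 0).
#' @param a Matching-law sensitivity (> 0).
#' @param beta_G,beta_H Softmax inverse temperatures (>= 0) for the
#'   goal-directed and habit values.
#' @param variant One of `"dual"`, `"goal_cu"`, `"goal_c"`, `"habit"`,
#'   `"goal_c_habit"`.
#' @return An object of class `dual_control_params`.
#' @export
dual_control_params <- function(alpha_c = 0.27, alpha_u = 0.05,
                                kappa = 3, a = 1.3,
                                beta_G = 1, beta_H = 1,
                                variant = "dual") {
  variant <- match.arg(variant, names(.dc_variants))
  stopifnot(alpha_c >= 0, alpha_c <= 1, alpha_u >= 0, alpha_u <= 1,
            kappa > 0, a > 0, beta_G >= 0, beta_H >= 0)
  structure(list(alpha_c = alpha_c, alpha_u = alpha_u, kappa = kappa,
                 a = a, beta_G = beta_G, beta_H = beta_H,
                 variant = variant,
                 k = length(.dc_variants[[variant]]$free)),
            class = "dual_control_params")
}

#' Habit value trajectory
#'
#' Leaky integration of the choice history:
#' `H_i(t) = sum_{s=1}^{t-1} exp(-s/kappa) * c_i(t-s)`, computed by the
#' equivalent recursion `H(t+1) = exp(-1/kappa) * (H(t) + c(t))` with
#' `H(1) = 0`. Under sustained choice of one option its habit value
#' saturates at `exp(-1/kappa) / (1 - exp(-1/kappa))`.
#'
#' @param options Choice sequence (character/factor/integer vector).
#' @param kappa Habit decay constant in trials (> 0).
#' @param option_set Option levels; defaults to distinct observed values.
#' @return Matrix of `length(options)` rows (trials) by options: the
#'   habit value *entering* each trial.
#' @export
habit_trajectory <- function(options, kappa, option_set = NULL) {
  stopifnot(kappa > 0)
  idx <- .option_index(options, option_set)
  K <- attr(idx, "K")
  N <- length(idx)
  d <- exp(-1 / kappa)
  H <- matrix(0, N, K, dimnames = list(NULL, attr(idx, "levels")))
  h <- numeric(K)
  for (t in seq_len(N)) {
    H[t, ] <- h
    ct <- numeric(K)
    ct[idx[t]] <- 1
    h <- d * (h + ct)
  }
  H
}

.option_index <- function(options, option_set = NULL) {
  if (inherits(options, "event_log")) {
    if (is.null(option_set)) option_set <- options$options
    options <- options$option
  }
  if (is.null(option_set)) option_set <- unique(as.character(options))
  idx <- match(as.character(options), option_set)
  if (anyNA(idx)) stop("options outside the declared option set")
  structure(idx, K = length(option_set), levels = option_set)
}

#' Reward values from choice rates via the generalized matching law
#'
#' Inverts the matching relation (choice ratios equal reward-value ratios
#' raised to the sensitivity `a`): `R_i` proportional to `rate_i^(1/a)`,
#' normalized so the largest reward value is 1.
#'
#' @param rates Per-option choice fractions (non-negative, summing to 1).
#' @param a Sensitivity parameter (> 0).
#' @return Numeric vector of reward values with max 1.
#' @export
#' @examples
#' reward_values(c(0.5, 0.25, 0.15, 0.10), a = 1)  # 1, 0.5, 0.3, 0.2
reward_values <- function(rates, a) {
  if (a <= 0) stop("sensitivity `a` must be positive")
  stopifnot(all(rates >= 0), abs(sum(rates) - 1) < 1e-8)
  R <- rates^(1 / a)
  R / max(R)
}

#' One goal-directed value update
#'
#' The chosen option moves toward its reward value by the prediction
#' error `delta_c = R_c - Q_c` at rate `alpha_c`; each unchosen option
#' decays toward 0 by `delta_u = -Q_u` at rate `alpha_u`.
#'
#' @param Q Numeric vector of current goal-directed values.
#' @param choice Index of the chosen option.
#' @param R_c Reward value of the chosen option.
#' @param alpha_c,alpha_u Learning/decay rates in `[0, 1]`.
#' @param decay_unchosen Apply the unchosen decay (default TRUE).
#' @return Updated `Q`.
#' @export
goal_step <- function(Q, choice, R_c, alpha_c, alpha_u,
                      decay_unchosen = TRUE) {
  Qn <- Q
  Qn[choice] <- Q[choice] + alpha_c * (R_c - Q[choice])
  if (decay_unchosen) {
    u <- setdiff(seq_along(Q), choice)
    Qn[u] <- Q[u] + alpha_u * (0 - Q[u])
  }
  Qn
}

#' Softmax choice probabilities from the two value systems
#'
#' `P_i` proportional to `exp(beta_G * Q_i + beta_H * H_i)`, computed
#' with max-subtraction so large values cannot overflow.
#'
#' @param Q,H Numeric vectors of goal-directed and habit values.
#' @param beta_G,beta_H Inverse temperatures (>= 0).
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(1, 0, 0, 0), rep(0, 4), beta_G = log(3),
#'                      beta_H = 0)  # 0.5, 1/6, 1/6, 1/6
choice_probabilities <- function(Q, H, beta_G, beta_H) {
  stopifnot(beta_G >= 0, beta_H >= 0, length(Q) == length(H))
  z <- beta_G * Q + beta_H * H
  e <- exp(z - max(z))
  e / sum(e)
}

#' Negative log-likelihood of a choice sequence
#'
#' Forward pass over trials: at each trial the current softmax
#' probability of the observed choice contributes `-log P`, then the
#' active systems update. Inactive systems under a nested variant are
#' masked (inverse temperature 0, updates skipped).
#'
#' @param options Choice sequence, or an [event_log()].
#' @param params A [dual_control_params()].
#' @param rewards Per-option reward values (same order as the option
#'   set).
#' @param option_set Option levels; defaults to distinct observed values.
#' @return The negative log-likelihood (natural log).
#' @export
sequence_nll <- function(options, params, rewards, option_set = NULL) {
  stopifnot(inherits(params, "dual_control_params"))
  idx <- .option_index(options, option_set)
  v <- .dc_variants[[params$variant]]
  stopifnot(length(rewards) == attr(idx, "K"))
  dc_nll(as.integer(idx), as.numeric(rewards),
         params$alpha_c, params$alpha_u, params$kappa,
         if (v$goal) params$beta_G else 0,
         if (v$habit) params$beta_H else 0,
         v$goal, v$habit, v$decay)
}

# Optimizer box for each free parameter. kappa and a are searched in
# log10 space (scale parameters); alphas and betas on their natural
# scale.
.dc_box <- list(
  alpha_c = c(1e-6, 1), alpha_u = c(1e-6, 1),
  a = log10(c(0.05, 20)), kappa = log10(c(0.5, 2000)),
  beta_G = c(0, 60), beta_H = c(0, 60))
.dc_log_scale <- c("a", "kappa")

.dc_vec_to_params <- function(theta, free, variant) {
  full <- list(alpha_c = 0, alpha_u = 0, kappa = 1, a = 1,
               beta_G = 0, beta_H = 0)
  for (j in seq_along(free)) {
    nm <- free[j]
    full[[nm]] <- if (nm %in% .dc_log_scale) 10^theta[j] else theta[j]
  }
  dual_control_params(alpha_c = full$alpha_c, alpha_u = full$alpha_u,
                      kappa = full$kappa, a = full$a,
                      beta_G = full$beta_G, beta_H = full$beta_H,
                      variant = variant)
}

#' Fit a dual-control choice model by maximum likelihood
#'
#' Bounded multi-start quasi-Newton (`L-BFGS-B`) minimization of
#' [sequence_nll()] over the variant's free parameters. Reward values are
#' recomputed inside the objective from the whole-session mean choice
#' rates and the candidate sensitivity `a` (held fixed at equal rewards
#' for the pure habit variant, where they are unused). The best restart
#' is returned.
#'
#' @param options Choice sequence, or an [event_log()].
#' @param variant Model variant (see [dual_control_params()]).
#' @param restarts Number of random restarts (>= 1, default 20).
#' @param seed Integer seed driving the restart draws.
#' @param rates Per-option choice fractions; default: observed
#'   frequencies.
#' @param option_set Option levels; defaults to distinct observed values.
#' @param init Optional warm starts: a [dual_control_params()] or a list
#'   of them (e.g. fitted nested variants), added to the random restart
#'   list. Warm-starting the full model from its nested models' optima
#'   guarantees the nested-likelihood ordering in practice.
#' @return Object of class `model_fit`: list with `params`, `nll`, `k`,
#'   `N`, `bic`, `pseudo_r2`, `converged`, `restarts`, `variant`,
#'   `rates`, `rewards`.
#' @export
fit_choice_model <- function(options, variant = "dual", restarts = 20,
                             seed = 1, rates = NULL, option_set = NULL,
                             init = NULL) {
  variant <- match.arg(variant, names(.dc_variants))
  stopifnot(restarts >= 1)
  idx <- .option_index(options, option_set)
  K <- attr(idx, "K")
  N <- length(idx)
  v <- .dc_variants[[variant]]
  free <- v$free
  if (is.null(rates))
    rates <- as.numeric(tabulate(idx, K)) / N
  lower <- vapply(free, function(nm) .dc_box[[nm]][1L], numeric(1))
  upper <- vapply(free, function(nm) .dc_box[[nm]][2L], numeric(1))

  objective <- function(theta) {
    p <- .dc_vec_to_params(theta, free, variant)
    rw <- if (v$goal) reward_values(rates, p$a) else rep(1, K)
    dc_nll(as.integer(idx), rw, p$alpha_c, p$alpha_u, p$kappa,
           if (v$goal) p$beta_G else 0, if (v$habit) p$beta_H else 0,
           v$goal, v$habit, v$decay)
  }

  params_to_theta <- function(p) {
    vapply(free, function(nm) {
      val <- p[[nm]]
      th <- if (nm %in% .dc_log_scale) log10(val) else val
      min(max(th, .dc_box[[nm]][1L]), .dc_box[[nm]][2L])
    }, numeric(1))
  }
  starts <- list()
  if (!is.null(init)) {
    if (inherits(init, "dual_control_params")) init <- list(init)
    if (inherits(init, "model_fit")) init <- list(init$params)
    starts <- lapply(init, function(p) {
      if (inherits(p, "model_fit")) p <- p$params
      stopifnot(inherits(p, "dual_control_params"))
      params_to_theta(p)
    })
  }

  set.seed(seed)
  best <- NULL
  any_converged <- FALSE
  for (r in seq_len(restarts + length(starts))) {
    start <- if (r <= length(starts)) starts[[r]]
             else lower + stats::runif(length(free)) * (upper - lower)
    res <- tryCatch(
      stats::optim(start, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e5, maxit = 400)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("fit error: all restarts failed")
  params <- .dc_vec_to_params(best$par, free, variant)
  rewards <- if (v$goal) reward_values(rates, params$a) else rep(1, K)
  nll <- best$value
  R0 <- N * log(1 / K)  # log-likelihood of the random-choice model
  structure(list(params = params, nll = nll, k = length(free), N = N,
                 bic = 2 * nll + length(free) * log(N),
                 pseudo_r2 = (R0 - (-nll)) / R0,
                 converged = any_converged, restarts = restarts,
                 seed = seed, variant = variant, rates = rates,
                 rewards = rewards),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<model_fit> %s: -LL = %.1f, k = %d, N = %d, BIC = %.1f, pseudo-r2 = %.3f\n",
    x$variant, x$nll, x$k, x$N, x$bic, x$pseudo_r2))
  cat(sprintf(
    "  alpha_c = %.3f, alpha_u = %.3f, a = %.2f, kappa = %.1f, beta_G = %.2f, beta_H = %.2f\n",
    p$alpha_c, p$alpha_u, p$a, p$kappa, p$beta_G, p$beta_H))
  invisible(x)
}

# Declared nestings: full -> nested variants obtainable by fixing
# parameters.
.dc_nestings <- list(
  dual = c("goal_cu", "goal_c", "habit", "goal_c_habit"),
  goal_cu = "goal_c",
  goal_c_habit = c("goal_c", "habit"))

#' Fit all dual-control variants with nested warm starts
#'
#' Fits the five model variants bottom-up: each fuller model receives
#' the optima of its nested submodels as additional starting points
#' (`goal_cu` and `goal_c_habit` start from `goal_c`/`habit`; `dual`
#' starts from all four). This guarantees in practice that a fuller
#' model never scores a worse likelihood than a model nested inside it,
#' which random multi-start alone does not.
#'
#' @inheritParams fit_choice_model
#' @param variants Which variants to fit (default: all five).
#' @return Named list of `model_fit` objects, ready for
#'   [compare_models()].
#' @export
fit_variant_suite <- function(options, restarts = 10, seed = 1,
                              rates = NULL, option_set = NULL,
                              variants = names(.dc_variants)) {
  fits <- list()
  inits <- list(
    goal_c = NULL, habit = NULL,
    goal_cu = c("goal_c"),
    goal_c_habit = c("goal_c", "habit"),
    dual = c("goal_cu", "goal_c_habit", "goal_c", "habit"))
  order <- intersect(c("goal_c", "habit", "goal_cu", "goal_c_habit",
                       "dual"), variants)
  for (v in order) {
    warm <- fits[intersect(inits[[v]], names(fits))]
    fits[[v]] <- fit_choice_model(options, v, restarts = restarts,
                                  seed = seed, rates = rates,
                                  option_set = option_set,
                                  init = unname(warm))
  }
  fits[intersect(variants, names(fits))]
}

#' Likelihood-ratio test between nested model fits
#'
#' `Lambda = 2 (LL_full - LL_nested)` compared to chi-square with
#' `k_full - k_nested` degrees of freedom. Refuses pairs that are not in
#' the declared nesting hierarchy.
#'
#' @param full,nested `model_fit` objects on the same data.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_test <- function(full, nested) {
  stopifnot(inherits(full, "model_fit"), inherits(nested, "model_fit"))
  if (full$N != nested$N)
    stop("fits are not on the same data (different N)")
  ok <- nested$variant %in% .dc_nestings[[full$variant]]
  if (!ok)
    stop("refusing likelihood-ratio test: `", nested$variant,
         "` is not nested in `", full$variant, "`")
  stat <- 2 * (nested$nll - full$nll)  # 2*(LL_full - LL_nested)
  df <- full$k - nested$k
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Compare fitted choice-model variants
#'
#' BIC per fit, likelihood-ratio tests of each nested variant against the
#' fullest model present (the `dual` variant when supplied), and the
#' winner by minimum BIC.
#'
#' @param fits List of `model_fit` objects on the same data.
#' @return Object of class `model_comparison`: data frame with columns
#'   `variant`, `nll`, `k`, `bic`, `delta_bic`, `pseudo_r2`,
#'   `lrt_statistic`, `lrt_df`, `lrt_p` (NA where no nesting applies),
#'   with attribute `winner`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "model_fit")))
  Ns <- vapply(fits, `[[`, numeric(1), "N")
  if (length(unique(Ns)) != 1L) stop("fits are not on the same data")
  variants <- vapply(fits, `[[`, character(1), "variant")
  names(fits) <- variants
  full_name <- if ("dual" %in% variants) "dual" else
    variants[which.max(vapply(fits, `[[`, numeric(1), "k"))]
  full <- fits[[full_name]]
  rows <- lapply(fits, function(f) {
    lrt <- if (f$variant != full_name &&
               f$variant %in% .dc_nestings[[full_name]]) {
      lrt_test(full, f)
    } else list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    data.frame(variant = f$variant, nll = f$nll, k = f$k, bic = f$bic,
               pseudo_r2 = f$pseudo_r2, lrt_statistic = lrt$statistic,
               lrt_df = lrt$df, lrt_p = lrt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$delta_bic <- out$bic - min(out$bic)
  out <- out[order(out$bic),
             c("variant", "nll", "k", "bic", "delta_bic", "pseudo_r2",
               "lrt_statistic", "lrt_df", "lrt_p")]
  attr(out, "winner") <- out$variant[1L]
  attr(out, "reference") <- full_name
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Simulate a choice sequence from the dual-control model
#'
#' Forward generative sampling: at each trial an option is drawn from the
#' current softmax probabilities, then the active value systems update
#' online, exactly mirroring [sequence_nll()].
#'
#' @param params A [dual_control_params()].
#' @param rewards Per-option reward values.
#' @param n_trials Number of trials to simulate.
#' @param seed Optional integer seed.
#' @param option_set Optional option labels (length matching `rewards`);
#'   default `O1..OK`.
#' @return Character vector of simulated choices.
#' @export
simulate_choices <- function(params, rewards, n_trials, seed = NULL,
                             option_set = NULL) {
  stopifnot(inherits(params, "dual_control_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- length(rewards)
  if (is.null(option_set)) option_set <- paste0("O", seq_len(K))
  stopifnot(length(option_set) == K)
  v <- .dc_variants[[params$variant]]
  u <- stats::runif(n_trials)
  idx <- dc_simulate(as.integer(n_trials), as.numeric(rewards),
                     params$alpha_c, params$alpha_u, params$kappa,
                     if (v$goal) params$beta_G else 0,
                     if (v$habit) params$beta_H else 0,
                     v$goal, v$habit, v$decay, u)
  option_set[idx]
}
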