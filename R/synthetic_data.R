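#' Configuration for a full synthetic foraging dataset
#'
#' Bundles the timing model, the choice model, the true reward values and
#' the session layout into one reproducible recipe. Defaults emulate the
#' study conditions the analysis targets: a 14-day session, four options
#' with rank-biased appeal, bursty timing (`tau_min` ~10 s, `tau0`
#' ~500 s, `mu` ~2) and nocturnal activity (dark-weighted hourly
#' profile).
#'
#' @param dual_state A [dual_state_params()]; default uses the
#'   dark-weighted hourly profile.
#' @param dual_control A [dual_control_params()].
#' @param rates True per-option long-run choice rates used to derive
#'   reward values through the matching law.
#' @param days Session length in days (default 14).
#' @param options Option labels (default four pellet flavors).
#' @param seed Integer seed; fixed seed gives byte-identical datasets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(dual_state = dual_state_params(
                               P_A = dark_weighted_profile()),
                             dual_control = dual_control_params(),
                             rates = c(0.5, 0.25, 0.15, 0.10),
                             days = 14,
                             options = c("chocolate", "banana",
                                         "coffee", "cinnamon"),
                             seed = 1) {
  stopifnot(inherits(dual_state, "dual_state_params"),
            inherits(dual_control, "dual_control_params"),
            length(options) >= 2, length(rates) == length(options),
            days > 0)
  structure(list(dual_state = dual_state, dual_control = dual_control,
                 rates = rates / sum(rates), days = days,
                 options = options, seed = seed),
            class = "synthetic_config")
}

#' Generate a complete synthetic foraging dataset
#'
#' Timestamps come from the dual-state timing simulator; options are then
#' assigned trial-by-trial by the dual-control choice simulator (the two
#' models are independent modules over the same event stream). Ground-
#' truth parameters travel with the log so recovery tests can score
#' themselves.
#'
#' @param config A [synthetic_config()].
#' @return An [event_log()] with attribute `truth`: list with the
#'   generating `dual_state`, `dual_control`, `rewards` and `rates`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  timing <- simulate_dual_state(config$dual_state,
                                duration = config$days * 86400)
  n <- length(timing$time)
  rewards <- reward_values(config$rates, config$dual_control$a)
  choices <- simulate_choices(config$dual_control, rewards, n,
                              option_set = config$options)
  log <- event_log(timing$time, choices,
                   schedule = config$dual_state$schedule,
                   options = config$options,
                   duration = timing$duration,
                   session_start = timing$session_start)
  attr(log, "truth") <- list(dual_state = config$dual_state,
                             dual_control = config$dual_control,
                             rewards = rewards, rates = config$rates)
  log
}

#' Generate simple interval or sequence fixtures
#'
#' Small named generators with known properties, used to pin analytic
#' identities: `hpp` (i.i.d. exponential intervals — Poisson timing,
#' burstiness near 0), `periodic` (constant intervals — burstiness
#' exactly -1), `alternating` (two alternating values — memory
#' coefficient -1), `powerlaw` (truncated power-law intervals),
#' `bimodal_ici` (mixture of a truncated power-law head and a Weibull
#' tail conditioned beyond the crossover, matching the dual-state
#' marginal).
#'
#' @param kind One of `"hpp"`, `"periodic"`, `"alternating"`,
#'   `"powerlaw"`, `"bimodal_ici"`.
#' @param n Number of intervals.
#' @param seed Optional integer seed.
#' @param rate Exponential rate for `hpp` (default 1).
#' @param value Constant interval for `periodic` (default 10).
#' @param values Two alternating intervals for `alternating`.
#' @param mu,tau_min,tau0 Power-law parameters for `powerlaw` and the
#'   `bimodal_ici` head.
#' @param lambda,gamma Weibull scale/shape for the `bimodal_ici` tail.
#' @param w_head Head weight of the `bimodal_ici` mixture.
#' @return Numeric vector of `n` intervals.
#' @export
generate_fixture <- function(kind, n, seed = NULL, rate = 1, value = 10,
                             values = c(1, 100), mu = 2, tau_min = 10,
                             tau0 = 500, lambda = 4160, gamma = 0.91,
                             w_head = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    hpp = stats::rexp(n, rate),
    periodic = rep(value, n),
    alternating = rep_len(values, n),
    powerlaw = qpowerlaw(stats::runif(n), mu, tau_min, tau0),
    bimodal_ici = {
      head <- stats::runif(n) < w_head
      out <- numeric(n)
      out[head] <- qpowerlaw(stats::runif(sum(head)), mu, tau_min, tau0)
      # Weibull conditioned on exceeding tau0 via inverse survival
      u <- stats::runif(sum(!head))
      out[!head] <- lambda * ((tau0 / lambda)^gamma - log(u))^(1 / gamma)
      out
    },
    stop("unknown fixture kind: ", kind))
}

#' Run the full analysis pipeline
#'
#' One call from a raw or synthetic log to the complete result bundle:
#' interval statistics (burstiness, memory, entropy trace,
#' autocorrelogram period), the bimodal interval fit, run/rank structure
#' with shuffle test, and — when enabled — the dual-state least-area
#' timing fit and the dual-control model comparison. Deterministic given
#' the configuration and seed.
#'
#' @param config A list with either `log` (path to a CSV event log) or
#'   `synthetic` (a [synthetic_config()]); optional entries: `seed`
#'   (default 1), `schedule` (a [cycle_schedule()]), `window` (entropy
#'   window, default 100), `bin_hours` (autocorrelogram bin, default 1),
#'   `n_shuffles` (default 999), `fit_timing` / `fit_choice` (logical,
#'   default FALSE; the expensive model-fitting stages), `timing_grid`
#'   (candidate grid for [least_area_fit()]), `choice_variants`
#'   (character vector of variants, default all five), `restarts`
#'   (default 10).
#' @param out_dir Optional directory: writes `summary.json` plus TSV
#'   tables (`icis.tsv`, `entropy_trace.tsv`, `autocorrelogram.tsv`,
#'   `runs.tsv`).
#' @return A list with elements `log`, `icis`, `burstiness`, `memory`,
#'   `entropy`, `autocorrelogram`, `bimodal` (NULL when no crossover),
#'   `ranks`, `rank_fit`, `runs`, `run_dist`, `shuffle_test`, and
#'   optionally `timing_fit`, `choice_fits`, `model_comparison`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.null(config$log) && is.null(config$synthetic))
    stop("configuration error: need `log` or `synthetic`")
  seed <- if (is.null(config$seed)) 1L else config$seed
  set.seed(seed)
  log <- if (!is.null(config$log)) {
    sch <- if (is.null(config$schedule)) cycle_schedule()
           else config$schedule
    read_event_log(config$log, schedule = sch)
  } else {
    stopifnot(inherits(config$synthetic, "synthetic_config"))
    if (is.null(config$synthetic$options))
      stop("configuration error: synthetic block lacks an option set")
    generate_dataset(config$synthetic)
  }
  window <- if (is.null(config$window)) 100 else config$window
  bin_hours <- if (is.null(config$bin_hours)) 1 else config$bin_hours
  n_shuffles <- if (is.null(config$n_shuffles)) 999 else config$n_shuffles

  icis <- interchoice_intervals(log)
  B <- burstiness(icis)
  M <- memory_coefficient(icis)
  entropy <- if (length(log$option) >= window)
    choice_entropy_trace(log, window) else NULL
  ac <- suppressWarnings(autocorrelogram_period(log, bin_hours))
  bimodal <- tryCatch(fit_bimodal(icis), error = function(e) NULL)
  ranks <- assign_ranks(log)
  rank_fit <- if (nrow(ranks) >= 3 && all(ranks$percent > 0))
    fit_rank_loglinear(ranks) else NULL
  runs <- extract_runs(log)
  run_dist <- run_distribution(runs)
  shuffle <- shuffle_run_test(log, n_shuffles = n_shuffles,
                              seed = seed + 1L)

  out <- list(log = log, icis = icis, burstiness = B, memory = M,
              entropy = entropy, autocorrelogram = ac, bimodal = bimodal,
              ranks = ranks, rank_fit = rank_fit, runs = runs,
              run_dist = run_dist, shuffle_test = shuffle)

  if (isTRUE(config$fit_timing)) {
    grid <- config$timing_grid
    if (is.null(grid))
      grid <- expand.grid(tau_min = min(icis$tau),
                          tau0 = c(300, 500, 800),
                          mu = c(1.8, 2.0, 2.2),
                          b_light = 1, b_dark = 1)
    out$timing_fit <- least_area_fit(log, grid, seed = seed + 2L)
  }
  if (isTRUE(config$fit_choice)) {
    variants <- if (is.null(config$choice_variants))
      c("dual", "goal_cu", "goal_c", "habit", "goal_c_habit")
      else config$choice_variants
    restarts <- if (is.null(config$restarts)) 10 else config$restarts
    out$choice_fits <- lapply(variants, function(v)
      fit_choice_model(log, v, restarts = restarts, seed = seed + 3L))
    out$model_comparison <- compare_models(out$choice_fits)
  }
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(data.frame(interval = res$icis$tau, cycle = res$icis$cycle),
      "icis.tsv")
  if (!is.null(res$entropy)) tsv(res$entropy, "entropy_trace.tsv")
  tsv(data.frame(lag_hours = res$autocorrelogram$lag_hours,
                 acf = res$autocorrelogram$acf),
      "autocorrelogram.tsv")
  tsv(as.data.frame(unclass(res$runs)), "runs.tsv")
  summ <- list(
    n_events = length(res$log$time),
    duration_days = res$log$duration / 86400,
    burstiness = res$burstiness, memory = res$memory,
    period_hours = res$autocorrelogram$period_hours,
    shuffle_p = res$shuffle_test$p_value,
    ranks = as.data.frame(unclass(res$ranks)))
  if (!is.null(res$rank_fit))
    summ$rank_slope <- res$rank_fit$slope
  if (!is.null(res$bimodal))
    summ$bimodal <- list(tau0 = res$bimodal$tau0,
                         mu = res$bimodal$head$mu,
                         tau_min = res$bimodal$head$tau_min,
                         lambda = res$bimodal$tail$lambda,
                         gamma = res$bimodal$tail$gamma,
                         w_head = res$bimodal$w_head)
  if (!is.null(res$model_comparison))
    summ$model_comparison <-
      as.data.frame(unclass(res$model_comparison))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
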