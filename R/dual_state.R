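#' Parameters of the dual-state timing model
#'
#' The dual-state model alternates between an *active* state — a burst of
#' choices whose intervals follow a truncated power law on
#' `[tau_min, tau0]` with exponent `mu` — and an *inactive* state, a long
#' gap generated by a non-homogeneous Poisson process whose rate is
#' modulated by the hour-of-day profile `P_A` raised to a cycle-specific
#' shape exponent (`b_light` in light hours, `b_dark` in dark). After each
#' choice the active state ends with probability `xi`, making burst
#' lengths geometric with mean `1/xi`.
#'
#' `rho0` is the mean inactive rate: the reciprocal of the mean
#' inactive-period (gap) duration. A gap is `tau0` plus the first
#' arrival of the modulated Poisson process, guaranteeing every gap
#' exceeds the burst separation threshold; the arrival rate is
#' `rho(t) = rho_arr * P_A(h(t))^b(h(t)) / Z`, where `Z` normalizes the
#' 24-hour time average of `P_A^b` to 1 and
#' `rho_arr = 1 / (1/rho0 - tau0)` compensates the `tau0` offset, so the
#' expected total gap is `1/rho0` and `rho0` keeps its stated meaning.
#' This requires `rho0 * tau0 < 1`.
#'
#' @param tau_min Smallest intra-burst interval, seconds.
#' @param tau0 Burst-separation threshold, seconds (`> tau_min`).
#' @param mu Power-law exponent, in (1, 3).
#' @param xi Per-choice probability of leaving the active state, in (0, 1].
#' @param rho0 Mean inactive rate, 1/seconds.
#' @param P_A Length-24 non-negative vector, probability of beginning an
#'   active state in each clock hour (hour 0 first); normalized to sum 1.
#' @param b_light,b_dark Shape exponents applied to `P_A` during light
#'   and dark hours.
#' @param schedule A [cycle_schedule()] defining which hours are light.
#' @return An object of class `dual_state_params`.
#' @export
dual_state_params <- function(tau_min = 10, tau0 = 500, mu = 2,
                              xi = 0.053, rho0 = 2.4e-4,
                              P_A = rep(1 / 24, 24),
                              b_light = 1, b_dark = 1,
                              schedule = cycle_schedule()) {
  stopifnot(tau_min > 0, tau0 > tau_min, mu > 1, mu < 3,
            xi > 0, xi <= 1, rho0 > 0, length(P_A) == 24,
            all(P_A >= 0), sum(P_A) > 0)
  if (rho0 * tau0 >= 1)
    stop("rho0 * tau0 must be < 1: the mean gap 1/rho0 cannot be ",
         "shorter than the burst-separation threshold tau0")
  structure(list(tau_min = tau_min, tau0 = tau0, mu = mu, xi = xi,
                 rho0 = rho0, P_A = P_A / sum(P_A),
                 b_light = b_light, b_dark = b_dark,
                 schedule = schedule),
            class = "dual_state_params")
}

#' Hour-of-day activity profile concentrated in the dark cycle
#'
#' Convenience constructor for `P_A`: a fraction `dark_mass` of the
#' bout-start probability is spread uniformly over the 12 dark hours and
#' the remainder over the light hours, emulating nocturnal foraging.
#'
#' @param dark_mass Total probability assigned to dark hours (default
#'   0.85).
#' @param schedule A [cycle_schedule()].
#' @return Length-24 probability vector (hour 0 first).
#' @export
dark_weighted_profile <- function(dark_mass = 0.85,
                                  schedule = cycle_schedule()) {
  hours <- 0:23
  since_onset <- (hours - schedule$light_onset) %% schedule$period
  light <- since_onset < schedule$light_hours
  p <- numeric(24)
  p[light] <- (1 - dark_mass) / sum(light)
  p[!light] <- dark_mass / sum(!light)
  p
}

#' Segment an event log into bursts and gaps
#'
#' Consecutive events whose interval is below `tau0` share a burst
#' (active state); an interval of `tau0` or more ends the burst, and the
#' gap is the time from the last event of one burst to the first event of
#' the next.
#'
#' @param log An [event_log()].
#' @param tau0 Burst-separation threshold, seconds.
#' @return Object of class `state_segmentation`: list with `bouts` (data
#'   frame: `first`, `last`, `n_events`, `start_hour`) and `gaps` (data
#'   frame: `duration`, `end_hour` — the clock hour at which the next
#'   burst begins).
#' @export
#' @examples
#' log <- event_log(c(0, 5, 10, 610, 615), rep("A", 5))
#' segment_states(log, 100)
segment_states <- function(log, tau0) {
  stopifnot(inherits(log, "event_log"), tau0 > 0)
  n <- length(log$time)
  breaks <- if (n > 1L) which(diff(log$time) >= tau0) else integer(0)
  first <- c(1L, breaks + 1L)
  last <- c(breaks, n)
  bouts <- data.frame(first = first, last = last,
                      n_events = last - first + 1L,
                      start_hour = clock_hour(log, log$time[first]))
  gaps <- data.frame(
    duration = log$time[first[-1L]] - log$time[last[-length(last)]],
    end_hour = clock_hour(log, log$time[first[-1L]]))
  structure(list(bouts = bouts, gaps = gaps, tau0 = tau0),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("<state_segmentation> ", nrow(x$bouts), " bouts, ",
      nrow(x$gaps), " gaps (tau0 = ", x$tau0, " s)\n", sep = "")
  invisible(x)
}

#' Estimate dual-state observables from a segmentation
#'
#' From the burst/gap decomposition: the transition probability
#' `xi = n_bouts / n_events` (maximum-likelihood estimate for geometric
#' burst lengths), the mean inactive rate `rho0 = 1 / mean(gap)`, and the
#' hour-of-day profile `P_A` as the normalized histogram of burst-start
#' clock hours.
#'
#' @param log An [event_log()].
#' @param seg A [segment_states()] result for that log.
#' @return List with `xi`, `rho0`, `P_A` (length 24).
#' @export
estimate_observables <- function(log, seg) {
  stopifnot(inherits(seg, "state_segmentation"))
  if (nrow(seg$bouts) < 2L)
    stop("insufficient segmentation: need at least 2 bouts")
  xi <- nrow(seg$bouts) / sum(seg$bouts$n_events)
  rho0 <- 1 / mean(seg$gaps$duration)
  hh <- floor(seg$bouts$start_hour) %% 24
  P_A <- tabulate(hh + 1L, nbins = 24)
  list(xi = xi, rho0 = rho0, P_A = P_A / sum(P_A))
}

#' Sample truncated power-law intervals
#'
#' Inverse-CDF sampling of intervals with density proportional to
#' `x^(-mu)` on `[tau_min, tau0]`.
#'
#' @param n Number of draws.
#' @param mu Exponent (> 1).
#' @param tau_min,tau0 Support bounds, seconds.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` intervals.
#' @export
sample_truncated_powerlaw <- function(n, mu, tau_min, tau0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qpowerlaw(stats::runif(n), mu, tau_min, tau0)
}

# Mean NHPP arrival rate compensating the tau0 gap offset, so that the
# expected total gap tau0 + arrival is 1/rho0.
.arrival_rate <- function(params) 1 / (1 / params$rho0 - params$tau0)

# Modulated arrival rate at absolute time t (seconds from session
# start), given the session's starting clock hour.
modulated_rate <- function(params, t, session_start) {
  h <- floor((session_start + t / 3600) %% 24)
  sch <- params$schedule
  light <- ((h - sch$light_onset) %% sch$period) < sch$light_hours
  b <- ifelse(light, params$b_light, params$b_dark)
  w <- params$P_A[h + 1L]^b
  .arrival_rate(params) * w / .rate_norm(params)
}

# Z: 24-h time average of P_A^b, so rho0 stays the mean inactive rate.
.rate_norm <- function(params) {
  sch <- params$schedule
  h <- 0:23
  light <- ((h - sch$light_onset) %% sch$period) < sch$light_hours
  b <- ifelse(light, params$b_light, params$b_dark)
  mean(params$P_A^b)
}

#' Sample one inactive gap duration
#'
#' The gap is `tau0` plus the first arrival of the non-homogeneous
#' Poisson process with the circadian-modulated arrival rate, sampled
#' by thinning against the peak rate. The rate is evaluated at true clock
#' time, so gaps beginning at different hours have different expected
#' lengths. With a uniform `P_A` the gap reduces to `tau0` plus an
#' exponential with rate `1/(1/rho0 - tau0)`, making the mean gap
#' exactly `1/rho0`.
#'
#' @param params A [dual_state_params()].
#' @param start Absolute gap start, seconds from session start.
#' @param session_start Clock hour of session start.
#' @param seed Optional integer seed.
#' @return Gap duration in seconds (always `>= tau0`).
#' @export
sample_inactive_gap <- function(params, start = 0,
                                session_start = params$schedule$light_onset,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- .rate_norm(params)
  sch <- params$schedule
  h <- 0:23
  light <- ((h - sch$light_onset) %% sch$period) < sch$light_hours
  b <- ifelse(light, params$b_light, params$b_dark)
  wmax <- max(params$P_A^b)
  if (wmax == 0) stop("no arrival: modulated rate is zero everywhere")
  rho_max <- .arrival_rate(params) * wmax / Z
  t <- start + params$tau0
  repeat {
    t <- t + stats::rexp(1, rho_max)
    rate <- modulated_rate(params, t, session_start)
    if (stats::runif(1) <= rate / rho_max) return(t - start)
  }
}

#' Simulate event timestamps from the dual-state model
#'
#' Starting in the inactive state, the simulator alternates: an inactive
#' gap ends with the first event of a burst; within the burst each
#' further interval is truncated power law, and after every event the
#' burst ends with probability `xi`. Simulation stops when the next event
#' would fall beyond `duration`.
#'
#' @param params A [dual_state_params()].
#' @param duration Total simulated seconds.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param session_start Clock hour of session start (default: light
#'   onset).
#' @return An [event_log()] with a single placeholder option `"X"`.
#' @export
simulate_dual_state <- function(params, duration, seed = NULL,
                                session_start =
                                  params$schedule$light_onset) {
  stopifnot(inherits(params, "dual_state_params"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  chunk <- numeric(4096)
  k <- 0L
  push <- function(x) {
    k <<- k + 1L
    if (k > length(chunk)) chunk <<- c(chunk, numeric(length(chunk)))
    chunk[k] <<- x
  }
  t <- 0
  repeat {
    gap <- sample_inactive_gap(params, t, session_start)
    t <- t + gap
    if (t > duration) break
    push(t)  # first event of the burst is the arrival itself
    repeat {
      if (stats::runif(1) < params$xi) break
      t <- t + qpowerlaw(stats::runif(1), params$mu,
                         params$tau_min, params$tau0)
      if (t > duration) break
      push(t)
    }
    if (t > duration) break
  }
  if (k == 0L) stop("no events generated within the requested duration")
  event_log(chunk[seq_len(k)], rep("X", k), schedule = params$schedule,
            duration = duration, session_start = session_start)
}

#' Area between two survival curves in log-log scale
#'
#' Integrates `|log10 S1 - log10 S2|` over `log10 t` on a common grid
#' spanning the overlap of the two supports (trapezoid rule), restricted
#' to grid points where both curves are positive. Symmetric in its
#' arguments; 0 iff the curves agree on the overlap.
#'
#' @param s1,s2 [survival_curve()] objects (or positive samples, which
#'   are converted).
#' @param n_grid Number of log-spaced grid points (default 200).
#' @return The non-negative area statistic.
#' @export
loglog_area <- function(s1, s2, n_grid = 200) {
  if (!inherits(s1, "survival_curve")) s1 <- survival_curve(s1)
  if (!inherits(s2, "survival_curve")) s2 <- survival_curve(s2)
  lo <- max(min(s1$x), min(s2$x))
  hi <- min(max(s1$x), max(s2$x))
  if (lo >= hi) stop("survival curves have disjoint supports")
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  a <- survival_at(s1, grid)
  b <- survival_at(s2, grid)
  keep <- a > 0 & b > 0
  if (sum(keep) < 2L) stop("no overlapping positive support")
  lx <- log10(grid[keep])
  dy <- abs(log10(a[keep]) - log10(b[keep]))
  sum(diff(lx) * (dy[-1L] + dy[-length(dy)]) / 2)
}

# Average survival of several samples, evaluated on a common log grid and
# returned as a survival_curve.
.mean_survival <- function(samples, n_grid = 200) {
  lo <- max(vapply(samples, min, numeric(1)))
  hi <- min(vapply(samples, max, numeric(1)))
  if (lo >= hi) return(NULL)
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  S <- rowMeans(vapply(samples,
                       function(s) survival_at(survival_curve(s), grid),
                       numeric(length(grid))))
  out <- data.frame(x = grid, S = S)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Least-area estimation of dual-state free parameters
#'
#' For each candidate parameter set (`tau_min`, `tau0`, `mu`, `b_light`,
#' `b_dark`), the log is segmented at the candidate `tau0`, the
#' observables (`xi`, `rho0`, `P_A`) are estimated from the segmentation,
#' `n_sim` replicate time series are simulated, and the candidate is
#' scored by the log-log area between the empirical interval survival and
#' the average simulated survival. The candidate with the smallest area
#' wins.
#'
#' @param log An [event_log()].
#' @param grid Data frame of candidates with columns `tau_min`, `tau0`,
#'   `mu`, `b_light`, `b_dark` (build with [expand.grid()]).
#' @param n_sim Simulated replicates per candidate (default 10).
#' @param seed Integer seed; the search trace is reproducible.
#' @param schedule A [cycle_schedule()].
#' @return Object of class `least_area_fit`: list with `best` (the
#'   winning row plus estimated `xi`, `rho0`), `area` (winning area),
#'   `trace` (all candidates with areas), `seed`.
#' @export
least_area_fit <- function(log, grid, n_sim = 10, seed = 1,
                           schedule = log$schedule) {
  stopifnot(inherits(log, "event_log"),
            all(c("tau_min", "tau0", "mu", "b_light", "b_dark")
                %in% names(grid)))
  emp <- survival_curve(diff(log$time))
  areas <- rep(NA_real_, nrow(grid))
  obs_list <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seg <- segment_states(log, g$tau0)
    if (nrow(seg$bouts) < 2L) {
      warning("candidate ", i, ": degenerate segmentation, skipped")
      next
    }
    obs <- estimate_observables(log, seg)
    obs_list[[i]] <- obs
    params <- tryCatch(
      dual_state_params(tau_min = g$tau_min, tau0 = g$tau0,
                        mu = g$mu, xi = obs$xi, rho0 = obs$rho0,
                        P_A = pmax(obs$P_A, 1e-12),
                        b_light = g$b_light, b_dark = g$b_dark,
                        schedule = schedule),
      error = function(e) NULL)
    if (is.null(params)) {
      warning("candidate ", i, ": invalid parameter combination, skipped")
      next
    }
    sims <- vector("list", n_sim)
    for (r in seq_len(n_sim)) {
      sim <- simulate_dual_state(params, log$duration,
                                 seed = seed + 1000L * i + r,
                                 session_start = log$session_start)
      sims[[r]] <- diff(sim$time)
    }
    avg <- .mean_survival(sims)
    if (is.null(avg)) next
    areas[i] <- tryCatch(loglog_area(emp, avg), error = function(e) NA)
  }
  if (all(is.na(areas))) stop("no candidate could be evaluated")
  best_i <- which.min(areas)
  best <- c(as.list(grid[best_i, ]), obs_list[[best_i]][c("xi", "rho0")])
  structure(list(best = best, area = areas[best_i],
                 trace = cbind(grid, area = areas), seed = seed),
            class = "least_area_fit")
}

#' @export
print.least_area_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<least_area_fit> area = %.4f | tau_min = %.3g, tau0 = %.3g, mu = %.3f, b_light = %.2f, b_dark = %.2f | xi = %.3g, rho0 = %.3g\n",
    x$area, b$tau_min, b$tau0, b$mu, b$b_light, b$b_dark, b$xi, b$rho0))
  invisible(x)
}
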