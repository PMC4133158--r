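test_that("segmentation groups events by the interval threshold", {
  log <- event_log(c(0.5, 5.5, 10.5, 610.5, 615.5), rep("A", 5))
  seg <- segment_states(log, 100)
  expect_equal(nrow(seg$bouts), 2L)
  expect_equal(seg$bouts$n_events, c(3L, 2L))
  expect_equal(seg$gaps$duration, 600)
  # all intervals below the threshold: one bout, no gaps
  seg1 <- segment_states(event_log(c(1, 2, 3), rep("A", 3)), 100)
  expect_equal(nrow(seg1$bouts), 1L)
  expect_equal(nrow(seg1$gaps), 0L)
  # gaps always >= tau0 by construction
  set.seed(51)
  tt <- cumsum(rexp(500, 1 / 50))
  segr <- segment_states(event_log(tt, rep("A", 500)), 120)
  expect_true(all(segr$gaps$duration >= 120))
  expect_equal(sum(segr$bouts$n_events), 500L)
})

test_that("observable estimators follow their definitions", {
  # 10 bouts over 100 events -> xi = 0.1; constructed log
  times <- numeric(0)
  t <- 0
  for (b in 1:10) {
    times <- c(times, t + cumsum(rep(5, 10)))
    t <- max(times) + 2000
  }
  log <- event_log(times, rep("A", 100))
  seg <- segment_states(log, 500)
  obs <- estimate_observables(log, seg)
  expect_equal(obs$xi, 0.1)
  expect_equal(obs$rho0, 1 / mean(seg$gaps$duration))
  expect_equal(sum(obs$P_A), 1)
  expect_error(estimate_observables(log, segment_states(log, 1e9)),
               "insufficient")
})

test_that("truncated power-law sampler matches the analytic CDF", {
  expect_equal(qpowerlaw(0, 2, 10, 500), 10)
  expect_equal(qpowerlaw(1, 2, 10, 500), 500)
  x <- sample_truncated_powerlaw(1e5, 2, 10, 500, seed = 52)
  expect_true(all(x >= 10 & x <= 500))
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) ppowerlaw(q, 2, 10, 500)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("inactive gaps reduce to tau0 + exponential under a flat profile", {
  p <- dual_state_params(tau0 = 500, rho0 = 1e-3)
  set.seed(53)
  gaps <- replicate(3000, sample_inactive_gap(p, start = 0))
  expect_true(all(gaps >= 500))
  # mean total gap is 1/rho0: rho0 is the reciprocal mean gap duration
  expect_equal(mean(gaps), 1000, tolerance = 0.05)
  # arrival beyond tau0 is exponential at the offset-compensated rate
  ks <- suppressWarnings(stats::ks.test(gaps - 500, "pexp",
                                        1 / (1 / 1e-3 - 500)))
  expect_gt(ks$p.value, 0.01)
  # mean gap shorter than tau0 is rejected as inconsistent
  expect_error(dual_state_params(tau0 = 500, rho0 = 3e-3),
               "rho0 \\* tau0")
})

test_that("a dark-only profile forbids bout starts in the light cycle", {
  p <- dual_state_params(P_A = dark_weighted_profile(1), xi = 0.05)
  sim <- simulate_dual_state(p, 14 * 86400, seed = 54)
  seg <- segment_states(sim, p$tau0)
  sch <- p$schedule
  start_h <- floor(seg$bouts$start_hour[-1])  # first bout inherits t=0
  in_light <- ((start_h - sch$light_onset) %% 24) < sch$light_hours
  expect_false(any(in_light))
  # and the dark cycle dominates overall activity
  lab <- assign_cycle_labels(sim)
  expect_gt(mean(lab == "dark"), mean(lab == "light"))
})

test_that("simulated bursts are geometric and observables are recovered", {
  p <- dual_state_params(xi = 0.05, rho0 = 5e-4, tau0 = 500)
  sim <- simulate_dual_state(p, 40 * 86400, seed = 55)
  seg <- segment_states(sim, 500)
  n_bouts <- nrow(seg$bouts)
  obs <- estimate_observables(sim, seg)
  # mean bout length within 2 s.e. of 1/xi (geometric sd ~ sqrt(1-xi)/xi)
  mean_len <- mean(seg$bouts$n_events)
  se <- sqrt(1 - 0.05) / 0.05 / sqrt(n_bouts)
  expect_lt(abs(mean_len - 20), 2 * se)
  expect_equal(obs$rho0, 5e-4, tolerance = 0.1)
})

test_that("log-log area statistic matches analytic values", {
  # untruncated mu = 2 power law: log-log survival has slope exactly -1,
  # so a x10 time shift separates the curves by exactly one decade
  x <- qpowerlaw(seq(0.0005, 0.9995, length.out = 2000), 2, 10)
  s1 <- survival_curve(x)
  expect_equal(loglog_area(s1, s1), 0)
  # time-rescaled copy of a slope -1 log-log curve: |dlogS| = 1 decade
  s2 <- survival_curve(10 * x)
  a <- loglog_area(s1, s2, n_grid = 500)
  lo <- max(min(s1$x), min(s2$x)); hi <- min(max(s1$x), max(s2$x))
  expect_equal(a, (log10(hi) - log10(lo)) * 1, tolerance = 0.05)
  expect_equal(loglog_area(s1, s2), loglog_area(s2, s1))
  expect_error(loglog_area(survival_curve(1:5),
                           survival_curve(100:105)), "disjoint")
})

test_that("least-area search honors its argmin contract and is reproducible", {
  p <- dual_state_params(mu = 2, tau0 = 500, xi = 0.05,
                         P_A = dark_weighted_profile(0.85))
  sim <- simulate_dual_state(p, 7 * 86400, seed = 56)
  grid <- expand.grid(tau_min = 10, tau0 = c(300, 500),
                      mu = c(1.7, 2.0, 2.4), b_light = 1, b_dark = 1)
  fit1 <- least_area_fit(sim, grid, n_sim = 3, seed = 57)
  expect_true(fit1$area <= min(fit1$trace$area, na.rm = TRUE))
  fit2 <- least_area_fit(sim, grid, n_sim = 3, seed = 57)
  expect_identical(fit1$trace$area, fit2$trace$area)
  expect_identical(fit1$best$mu, fit2$best$mu)
})
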