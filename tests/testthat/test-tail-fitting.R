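test_that("survival curve matches counting and the 1-ECDF convention", {
  sc <- survival_curve(c(1, 2, 2, 4))
  expect_equal(sc$x, c(1, 2, 4))
  expect_equal(sc$S, c(1, 0.75, 0.25))
  expect_equal(survival_at(sc, c(0.5, 1, 1.5, 2, 3, 4, 5)),
               c(1, 1, 0.75, 0.75, 0.25, 0.25, 0))
  expect_equal(survival_curve(7)$S, 1)
  # enumeration oracle on random data: S(x) = mean(values >= x)
  set.seed(21)
  v <- sample(1:20, 100, TRUE)
  sc2 <- survival_curve(v)
  grid <- seq(0, 25, by = 0.5)
  expect_equal(survival_at(sc2, grid),
               vapply(grid, function(g) mean(v >= g), numeric(1)))
})

test_that("power-law MLE: closed form, numeric agreement, and recovery", {
  f <- fit_powerlaw(c(2, 4, 8), tau_min = 2, min_tail = 3)
  expect_equal(f$mu, 1 + 3 / (3 * log(2)), tolerance = 1e-12)
  # closed form equals the numerical truncated optimizer as tau0 -> Inf
  set.seed(22)
  x <- qpowerlaw(runif(500), 2.2, 5)
  closed <- fit_powerlaw(x, tau_min = 5)$mu
  numeric_fit <- fit_powerlaw(x, tau_min = 5, tau0 = max(x) * 1e6)$mu
  expect_equal(closed, numeric_fit, tolerance = 1e-6)
  # recovery at n = 1e4, absolute +/- 0.05 on the exponent
  x2 <- sample_truncated_powerlaw(1e4, 2, 10, Inf, seed = 23)
  expect_lt(abs(fit_powerlaw(x2, tau_min = 10)$mu - 2), 0.05)
  # truncated recovery
  x3 <- sample_truncated_powerlaw(1e4, 2, 10, 500, seed = 24)
  expect_lt(abs(fit_powerlaw(x3, tau_min = 10, tau0 = 500)$mu - 2),
            0.05)
  expect_error(fit_powerlaw(rep(3, 5), tau_min = 10),
               "insufficient tail")
})

test_that("KS scan picks a sensible lower bound", {
  # data that are power law only above tau_min = 50
  set.seed(25)
  x <- c(runif(2000, 1, 50), qpowerlaw(runif(2000), 2, 50))
  f <- fit_powerlaw(x, tau_min = "scan")
  expect_gt(f$tau_min, 20)
  expect_lt(f$tau_min, 120)
  expect_equal(f$mu, 2, tolerance = 0.15)
  # exponential sample: scan is driven deep into the tail
  set.seed(26)
  e <- rexp(5000, 1 / 100)
  fe <- fit_powerlaw(e, tau_min = "scan")
  expect_gt(fe$tau_min, stats::median(e))
})

test_that("Weibull MLE recovers shape and scale", {
  set.seed(27)
  w1 <- fit_weibull(rexp(1e4, 1 / 100))
  expect_equal(w1$gamma, 1, tolerance = 0.05)
  expect_equal(w1$lambda, 100, tolerance = 0.05)
  w2 <- fit_weibull(rweibull(1e4, 1.23, 2740))
  expect_equal(w2$gamma, 1.23, tolerance = 0.05)
  expect_equal(w2$lambda, 2740, tolerance = 0.05)
  expect_error(fit_weibull(rep(4, 100)), "degenerate")
  # left-truncated fit recovers the untruncated parameters
  set.seed(28)
  u <- runif(5000)
  xt <- 2740 * ((500 / 2740)^0.91 - log(u))^(1 / 0.91)  # conditional >= 500
  wt <- fit_weibull(xt, left = 500)
  expect_equal(wt$gamma, 0.91, tolerance = 0.1)
  expect_equal(wt$lambda, 2740, tolerance = 0.15)
})

test_that("bootstrap goodness of fit is calibrated and discriminates", {
  # data simulated from the fitted model: p roughly uniform
  set.seed(29)
  ps <- replicate(15, {
    x <- qpowerlaw(runif(400), 2, 10)
    f <- fit_powerlaw(x, tau_min = 10)
    gof_bootstrap(f, n_boot = 100)$p_gof
  })
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  # exponential data tested against a power law: p near 0
  set.seed(30)
  e <- 10 * (1 + rexp(1000, 1))
  fe <- fit_powerlaw(e, tau_min = 10)
  expect_lt(gof_bootstrap(fe, n_boot = 100)$p_gof, 0.05)
})

test_that("crossover detection finds the density valley and rejects unimodal data", {
  tau0s <- vapply(1:5, function(s)
    detect_tau0(generate_fixture("bimodal_ici", 2e4, seed = s)),
    numeric(1))
  expect_true(all(tau0s > 300 & tau0s < 1000))
  set.seed(31)
  expect_error(detect_tau0(rexp(2e4, 1 / 200)), "no crossover")
  expect_error(detect_tau0(rexp(100, 1 / 1e4) + 2000), "span")
})

test_that("bimodal piecewise fit recovers both components", {
  errs <- t(vapply(1:8, function(s) {
    mix <- generate_fixture("bimodal_ici", 2e4, seed = s)
    bf <- fit_bimodal(mix)
    c(bf$head$mu - 2, bf$tail$gamma - 0.91)
  }, numeric(2)))
  expect_lt(stats::median(abs(errs[, 1])), 0.1)
  expect_lt(stats::median(abs(errs[, 2])), 0.1)
  # composite survival: 1 at tau_min, non-increasing
  mix <- generate_fixture("bimodal_ici", 2e4, seed = 1)
  bf <- fit_bimodal(mix)
  expect_equal(bf$survival(bf$head$tau_min), 1)
  grid <- 10^seq(log10(bf$head$tau_min), log10(max(mix)),
                 length.out = 1000)
  S <- bf$survival(grid)
  expect_true(all(diff(S) <= 1e-12))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("per-cycle fits with shared crossover expose light/dark scale contrast", {
  # generator with longer gaps in light than dark: simulate timing with
  # cycle-dependent modulation, then fit per cycle
  p <- dual_state_params(P_A = dark_weighted_profile(0.85),
                         b_light = 1, b_dark = 1)
  sim <- simulate_dual_state(p, 14 * 86400, seed = 6)
  icis <- interchoice_intervals(sim)
  rep <- bimodal_report(icis)
  expect_equal(nrow(rep), 3L)
  light_lam <- rep$lambda[rep$cycle == "light"]
  dark_lam <- rep$lambda[rep$cycle == "dark"]
  expect_gt(light_lam, dark_lam)  # sparser light activity, longer gaps
  expect_equal(length(unique(rep$tau0)), 1L)  # detect-once-reuse
})
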