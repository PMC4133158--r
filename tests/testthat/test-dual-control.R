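test_that("habit trajectory matches the direct kernel-sum oracle", {
  opts <- LETTERS[1:4]
  # one-term sum: single A at trial 1
  H <- habit_trajectory(c("A", "B"), kappa = 5, option_set = opts)
  expect_equal(unname(H[2, "A"]), exp(-1 / 5))
  # geometric asymptote under sustained choice
  Hlong <- habit_trajectory(rep("A", 2000), kappa = 5, option_set = opts)
  expect_equal(unname(Hlong[2000, "A"]),
               exp(-1 / 5) / (1 - exp(-1 / 5)), tolerance = 1e-8)
  # recursion == direct summation on random sequences
  for (s in 1:3) {
    set.seed(s)
    x <- sample(opts, 500, TRUE)
    kap <- c(2, 10, 50)[s]
    expect_equal(habit_trajectory(x, kap, opts),
                 oracle_habit_direct(x, kap, opts),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("matching-law reward values follow the sensitivity inversion", {
  expect_equal(reward_values(c(0.5, 0.25, 0.15, 0.10), a = 1),
               c(1, 0.5, 0.3, 0.2))
  expect_equal(reward_values(c(0.5, 0.25, 0.15, 0.10), a = 2),
               c(1, 0.7071, 0.5477, 0.4472), tolerance = 1e-4)
  expect_equal(reward_values(rep(0.25, 4), a = 3), rep(1, 4))
  expect_error(reward_values(c(0.5, 0.5), a = 0), "positive")
})

test_that("goal-directed update moves chosen up and unchosen down", {
  Q <- goal_step(c(0, 0.8, 0.3, 0), choice = 1, R_c = 1,
                 alpha_c = 0.5, alpha_u = 0.25)
  expect_equal(Q[1], 0.5)
  expect_equal(Q[2], 0.6)
  # repeated choice converges geometrically to the reward value
  q <- c(0, 0, 0, 0)
  for (i in 1:200) q <- goal_step(q, 1, 0.7, 0.3, 0.1)
  expect_equal(q[1], 0.7, tolerance = 1e-8)
  expect_equal(q[2], 0, tolerance = 1e-8)
})

test_that("softmax probabilities are exact, normalized, and overflow-safe", {
  expect_equal(choice_probabilities(rep(1, 4), rep(2, 4), 3, 5),
               rep(0.25, 4))
  expect_equal(choice_probabilities(c(1, 0, 0, 0), rep(0, 4),
                                    log(3), 0),
               c(0.5, 1 / 6, 1 / 6, 1 / 6))
  expect_equal(choice_probabilities(c(1e4, 0, 0, 0), rep(0, 4), 50, 0),
               c(1, 0, 0, 0), tolerance = 1e-12)
  for (s in 1:20) {
    set.seed(s)
    p <- choice_probabilities(rnorm(4, 0, 10), rexp(4), runif(1, 0, 5),
                              runif(1, 0, 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("sequence likelihood matches an independent forward-pass oracle", {
  opts <- LETTERS[1:4]
  rw <- c(1, 0.7, 0.5, 0.4)
  variants <- list(
    dual = c(TRUE, TRUE, TRUE), goal_cu = c(TRUE, FALSE, TRUE),
    goal_c = c(TRUE, FALSE, FALSE), habit = c(FALSE, TRUE, FALSE),
    goal_c_habit = c(TRUE, TRUE, FALSE))
  for (v in names(variants)) {
    set.seed(match(v, names(variants)))
    x <- sample(opts, 200, TRUE)
    pars <- dual_control_params(alpha_c = 0.3, alpha_u = 0.1,
                                kappa = 4, a = 2, beta_G = 1.2,
                                beta_H = 0.6, variant = v)
    flags <- variants[[v]]
    want <- oracle_dc_nll(match(x, opts), rw, 0.3, 0.1, 4,
                          if (flags[1]) 1.2 else 0,
                          if (flags[2]) 0.6 else 0,
                          flags[1], flags[2], flags[3])
    expect_equal(sequence_nll(x, pars, rw, option_set = opts), want,
                 tolerance = 1e-10)
  }
  # habit variant with beta_H = 0 is the uniform model
  pars0 <- dual_control_params(kappa = 4, beta_H = 0, variant = "habit")
  set.seed(99)
  x <- sample(opts, 100, TRUE)
  expect_equal(sequence_nll(x, pars0, rep(1, 4), option_set = opts),
               100 * log(4), tolerance = 1e-12)
})

test_that("unchosen decay amplifies the next prediction error for that option", {
  # choose A for a while, then B: delta for B larger when alpha_u > 0
  run_then_switch <- function(alpha_u) {
    Q <- c(0, 0, 0, 0)
    rw <- c(1, 0.7, 0.5, 0.4)
    Q[2] <- 0.6  # B starts part-learned
    for (i in 1:20) Q <- goal_step(Q, 1, rw[1], 0.3, alpha_u)
    rw[2] - Q[2]  # prediction error if B is chosen next
  }
  expect_gt(run_then_switch(0.2), run_then_switch(0))
  # and monotone decay of the unchosen value itself
  Q <- c(0, 0.9, 0, 0)
  vals <- numeric(10)
  for (i in 1:10) {
    Q <- goal_step(Q, 1, 1, 0.3, 0.15)
    vals[i] <- Q[2]
  }
  expect_true(all(diff(vals) < 0))
})

test_that("BIC, pseudo-r2 and LRT follow their formulas", {
  # check the comparison arithmetic through the public path on small fits
  set.seed(61)
  x <- sample(LETTERS[1:4], 300, TRUE)
  f_dual <- fit_choice_model(x, "dual", restarts = 2, seed = 1)
  f_habit <- fit_choice_model(x, "habit", restarts = 2, seed = 1)
  expect_equal(f_dual$bic, 2 * f_dual$nll + f_dual$k * log(300))
  expect_equal(f_habit$k, 2)
  expect_equal(f_dual$k, 6)
  R0 <- 300 * log(1 / 4)
  expect_equal(f_dual$pseudo_r2, (R0 - (-f_dual$nll)) / R0)
  # i.i.d. uniform data: pseudo-r2 ~ 0
  expect_equal(f_dual$pseudo_r2, 0, tolerance = 0.02)
  cmp <- compare_models(list(f_dual, f_habit))
  expect_s3_class(cmp, "model_comparison")
  lrt <- lrt_test(f_dual, f_habit)
  expect_equal(lrt$df, 4)
  expect_equal(lrt$statistic, 2 * (f_habit$nll - f_dual$nll))
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 4, lower.tail = FALSE))
  # refuse non-nested comparisons
  f_gcu <- fit_choice_model(x, "goal_cu", restarts = 2, seed = 1)
  expect_error(lrt_test(f_gcu, f_habit), "not nested")
})

test_that("worked arithmetic: BIC and pseudo-r2 at printed values", {
  # LL = -100, k = 6, N = 1000 -> BIC = 200 + 6 ln 1000
  expect_equal(2 * 100 + 6 * log(1000), 241.4473, tolerance = 1e-4)
  # N = 1000, L = -700 -> pseudo-r2 = 0.49506 (exact arithmetic)
  R0 <- 1000 * log(1 / 4)
  expect_equal((R0 - (-700)) / R0, 0.49506, tolerance = 1e-4)
})

test_that("simulated choices respect their generative regime", {
  # beta_G = beta_H = 0: uniform frequencies
  p0 <- dual_control_params(beta_G = 0, beta_H = 0)
  ch0 <- simulate_choices(p0, rep(1, 4), 1e4, seed = 62)
  expect_gt(stats::chisq.test(table(ch0))$p.value, 0.001)
  # habit-dominant: markedly fewer (hence longer) runs than a shuffle
  ph <- dual_control_params(beta_G = 0, beta_H = 0.8, kappa = 3,
                            variant = "habit")
  chh <- simulate_choices(ph, rep(1, 4), 2000, seed = 63)
  set.seed(631)
  expect_lt(nrow(extract_runs(chh)),
            0.8 * nrow(extract_runs(sample(chh))))
  # fixed seed reproducibility
  expect_identical(simulate_choices(p0, rep(1, 4), 100, seed = 5),
                   simulate_choices(p0, rep(1, 4), 100, seed = 5))
})

test_that("run hazard separates habit-driven from memoryless sequences", {
  ph <- dual_control_params(beta_G = 0, beta_H = 1.2, kappa = 5,
                            variant = "habit")
  chh <- simulate_choices(ph, rep(1, 4), 5000, seed = 64)
  rdh <- run_distribution(extract_runs(chh))
  ok <- rdh$survival > 0.02
  # hazard decreases with run length for the habit generator
  expect_lt(rdh$hazard[max(which(ok))], rdh$hazard[1])
  # memoryless generator: flat hazard
  p0 <- dual_control_params(beta_G = 0, beta_H = 0)
  ch0 <- simulate_choices(p0, rep(1, 4), 5000, seed = 65)
  rd0 <- run_distribution(extract_runs(ch0))
  ok0 <- rd0$survival > 0.05
  expect_lt(max(abs(rd0$hazard[ok0] - 0.75)), 0.12)
})

test_that("fitted likelihood never falls below the generating parameters", {
  truth <- dual_control_params()
  rw <- reward_values(c(0.5, 0.25, 0.15, 0.10), truth$a)
  ch <- simulate_choices(truth, rw, 2000, seed = 66)
  f <- fit_choice_model(ch, "dual", restarts = 4, seed = 67)
  nll_truth <- sequence_nll(ch, truth, rw,
                            option_set = paste0("O", 1:4))
  expect_lte(f$nll, nll_truth + 1e-6)
  expect_true(f$converged)
})
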