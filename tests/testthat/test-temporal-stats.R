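test_that("interchoice intervals difference the timestamps and carry labels", {
  log <- event_log(c(0.5, 10.5, 30.5, 100.5), rep("A", 4))
  icis <- interchoice_intervals(log)
  expect_equal(icis$tau, c(10, 20, 70))
  expect_error(interchoice_intervals(event_log(1, "A")), "at least 2")
  # interval starting in dark is labeled dark (session starts at light onset)
  log2 <- event_log(c(11 * 3600, 13 * 3600, 14 * 3600), rep("A", 3))
  expect_equal(as.character(interchoice_intervals(log2)$cycle),
               c("light", "dark"))
})

test_that("burstiness matches its closed form and known limits", {
  expect_identical(burstiness(rep(5, 1000)), -1)
  # direct arithmetic with population sigma
  x <- c(10, 10, 10, 1000)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  expect_equal(burstiness(x), (s - m) / (s + m))
  expect_equal(burstiness(x), 0.24947, tolerance = 1e-4)
  # two-valued interval sets: closed form (s/m derived analytically)
  for (v in c(2, 10, 50)) {
    x2 <- rep(c(1, v), 50)
    m2 <- (1 + v) / 2; s2 <- (v - 1) / 2
    expect_equal(burstiness(x2), (s2 - m2) / (s2 + m2))
  }
  set.seed(11)
  expect_equal(burstiness(rexp(1e5)), 0, tolerance = 0.02)
})

test_that("memory coefficient matches the consecutive-pair correlation oracle", {
  expect_equal(memory_coefficient(1:5), 1)
  expect_equal(memory_coefficient(c(1, 100, 1, 100, 1)), -1)
  expect_error(memory_coefficient(rep(3, 10)), "zero variance")
  set.seed(12)
  expect_equal(memory_coefficient(rexp(1e5)), 0, tolerance = 0.02)
  # brute-force Pearson correlation over pairs, population normalization
  for (s in 1:5) {
    set.seed(s)
    x <- rlnorm(50)
    a <- x[-length(x)]; b <- x[-1]
    num <- mean((a - mean(a)) * (b - mean(b)))
    den <- sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2))
    expect_equal(memory_coefficient(x), num / den, tolerance = 1e-12)
  }
})

test_that("B and M are invariant to uniform time rescaling", {
  set.seed(13)
  x <- rlnorm(500)
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(burstiness(k * x), burstiness(x), tolerance = 1e-12)
    expect_equal(memory_coefficient(k * x), memory_coefficient(x),
                 tolerance = 1e-12)
  }
})

test_that("entropy trace hits its analytic values and bounds", {
  expect_equal(choice_entropy_trace(rep("A", 100), 100)$entropy, 0)
  u <- rep(LETTERS[1:4], 25)
  expect_equal(choice_entropy_trace(u, 100)$entropy, 2)
  mix <- c(rep("A", 50), rep("B", 25), rep("C", 25))
  expect_equal(choice_entropy_trace(mix, 100,
                                    option_set = LETTERS[1:4])$entropy,
               1.5)
  set.seed(14)
  seq4 <- sample(LETTERS[1:4], 1000, TRUE)
  expect_true(all(choice_entropy_trace(seq4, 100)$entropy <= 2))
})

test_that("persistent sequences have lower entropy than their shuffles", {
  seq_p <- rep(rep(LETTERS[1:4], each = 50), 4)  # runs of 50
  cmp <- entropy_shuffle_comparison(seq_p, window = 100,
                                    n_shuffles = 100, seed = 1)
  expect_true(mean(cmp$difference < 0) > 0.8)
  expect_true(cmp$mean_difference < 0)
  # exchangeable sequence: difference ~ 0
  set.seed(15)
  seq_i <- sample(LETTERS[1:4], 2000, TRUE)
  cmp_i <- entropy_shuffle_comparison(seq_i, 100, 100, seed = 2)
  expect_equal(cmp_i$mean_difference, 0, tolerance = 0.02)
  # seeded reproducibility
  cmp_a <- entropy_shuffle_comparison(seq_p, 100, 100, seed = 9)
  cmp_b <- entropy_shuffle_comparison(seq_p, 100, 100, seed = 9)
  expect_identical(cmp_a$shuffled_mean, cmp_b$shuffled_mean)
})

test_that("autocorrelogram recovers known periods and flags featureless records", {
  l24 <- oracle_sinusoid_log(24, 14, seed = 5)
  expect_equal(autocorrelogram_period(l24)$period_hours, 24,
               tolerance = 0.05)
  l12 <- oracle_sinusoid_log(12, 14, seed = 3)
  expect_equal(autocorrelogram_period(l12)$period_hours, 12,
               tolerance = 0.1)
  # homogeneous Poisson: no qualifying peaks
  set.seed(9)
  tt <- cumsum(rexp(5000, 5000 / (14 * 86400)))
  hp <- event_log(tt[tt < 14 * 86400], rep("X", sum(tt < 14 * 86400)),
                  duration = 14 * 86400)
  expect_warning(ac <- autocorrelogram_period(hp), "period undefined")
  expect_false(ac$period_defined)
  expect_true(is.na(ac$period_hours))
})
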