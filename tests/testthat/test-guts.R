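test_that("sub-threshold exposure reduces both models to background", {
  times <- c(12, 24, 48)
  sd_p <- guts_params_sd(k_d = 0.1, h_b = 0.002, z = 0.05, k_k = 10)
  it_p <- guts_params_it(k_d = 0.1, h_b = 0.002, alpha = 0.05, beta = 5)

  # damage never exceeds z = 0.05 under constant 0.04
  prof <- exposure_constant(0.04)
  expect_equal(survival_sd(sd_p, prof, times)$survival,
               exp(-0.002 * times), tolerance = 1e-12)

  # zero exposure: SD and IT agree exactly
  zero <- exposure_constant(0)
  expect_equal(survival_sd(sd_p, zero, times)$survival,
               survival_it(it_p, zero, times)$survival, tolerance = 1e-14)

  # no background, sub-threshold: certain survival
  sd0 <- guts_params_sd(k_d = 0.1, h_b = 0, z = 0.05, k_k = 10)
  expect_equal(survival_sd(sd0, prof, 48)$survival, 1)
})

test_that("SD survival matches a dense Euler integration oracle", {
  p <- guts_params("thiacloprid", "sd")
  # strong exposure (expected value frozen from the oracle): survival
  # collapses by 48 h
  s_strong <- survival_sd(p, exposure_constant(0.1), 48)$survival
  oracle_strong <- euler_survival_sd(p, exposure_constant(0.1), 48)
  expect_equal(s_strong, oracle_strong, tolerance = 1e-4)
  expect_lt(abs(log(s_strong) - log(oracle_strong)), 0.01)

  # intermediate exposure near the threshold
  s_mid <- survival_sd(p, exposure_constant(0.02), c(24, 48))$survival
  oracle_mid <- euler_survival_sd(p, exposure_constant(0.02), c(24, 48))
  expect_equal(s_mid, oracle_mid, tolerance = 1e-3)

  # pulsed exposure
  pp <- make_pulse_profile(0.05, 8, c(0, 1))
  s_pulse <- survival_sd(p, pp, c(4, 8, 24, 32, 48))$survival
  oracle_pulse <- euler_survival_sd(p, pp, c(4, 8, 24, 32, 48))
  expect_equal(s_pulse, oracle_pulse, tolerance = 1e-3)
})

test_that("IT survival follows the log-logistic threshold distribution", {
  p <- guts_params("imidacloprid", "it")
  # steady state: max damage -> c, survival ratio -> 1 - F(c)
  t_long <- 2000
  s <- survival_it(p, exposure_constant(0.2, t_end = t_long),
                   t_long)$survival
  expect_equal(s / exp(-p$h_b * t_long),
               1 - 1 / (1 + (0.2 / p$alpha)^(-p$beta)), tolerance = 1e-8)

  # when max damage equals the median threshold, half die of the toxicant
  k_d <- 0.2; t_obs <- 10
  conc <- p$alpha / (1 - exp(-k_d * t_obs))
  p2 <- guts_params_it(k_d, 0.001, p$alpha, p$beta)
  s2 <- survival_it(p2, exposure_constant(conc, t_end = t_obs),
                    t_obs)$survival
  expect_equal(s2, 0.5 * exp(-0.001 * t_obs), tolerance = 1e-9)
})

test_that("survival curves are monotone and bounded for random parameters", {
  set.seed(11)
  prof <- make_pulse_profile(0.5, 8, c(0, 1))
  tt <- c(seq(2, 48, by = 2))
  for (i in 1:15) {
    sd_p <- guts_params_sd(10^runif(1, -3, 1), runif(1, 0, 0.01),
                           10^runif(1, -3, 0), 10^runif(1, -2, 2))
    it_p <- guts_params_it(10^runif(1, -3, 1), runif(1, 0, 0.01),
                           10^runif(1, -3, 0), 10^runif(1, 0, 1.5))
    for (s in list(survival_sd(sd_p, prof, tt)$survival,
                   survival_it(it_p, prof, tt)$survival)) {
      expect_true(all(s >= 0 & s <= 1))
      expect_true(all(diff(s) <= 1e-12))
    }
  }
})

test_that("Monte-Carlo individual simulation reproduces both models", {
  set.seed(101)
  n <- 2e4
  sd_p <- guts_params("thiacloprid", "sd")
  it_p <- guts_params("thiacloprid", "it")
  prof <- make_pulse_profile(0.08, 8, c(0, 1))
  times <- c(8, 24, 48)

  s_model <- survival_sd(sd_p, prof, times)$survival
  s_mc <- mc_survival_sd(sd_p, prof, times, n)
  se <- sqrt(pmax(s_model * (1 - s_model), 1e-12) / n)
  expect_true(all(abs(s_mc - s_model) <= 3 * se + 2 / n))

  s_model_it <- survival_it(it_p, prof, times)$survival
  s_mc_it <- mc_survival_it(it_p, prof, times, n)
  se_it <- sqrt(pmax(s_model_it * (1 - s_model_it), 1e-12) / n)
  expect_true(all(abs(s_mc_it - s_model_it) <= 3 * se_it + 2 / n))
})

test_that("lcx converges to the incipient thresholds and is monotone", {
  sd_p <- guts_params("thiacloprid", "sd")
  it_p <- guts_params("thiacloprid", "it")

  expect_equal(lcx(sd_p, x = 50, t = 1e4), sd_p$z, tolerance = 0.01)
  expect_equal(lcx(it_p, x = 50, t = 1e4), it_p$alpha, tolerance = 0.01)

  # closed-form finite-time inversion for IT: max damage = c (1 - e^-1)
  p <- guts_params_it(k_d = 1, h_b = 0, alpha = 0.05, beta = 8)
  expect_equal(lcx(p, x = 50, t = 1), 0.05 / (1 - exp(-1)),
               tolerance = 1e-5)

  # apparent sensitivity increases with exposure time
  lc_24 <- lcx(sd_p, x = 50, t = 24)
  lc_48 <- lcx(sd_p, x = 50, t = 48)
  lc_96 <- lcx(sd_p, x = 50, t = 96)
  expect_true(lc_24 >= lc_48 && lc_48 >= lc_96)

  # unreachable effect: a template with zero concentration cannot kill
  expect_error(lcx(sd_p, x = 50, t = 48,
                   template = exposure_constant(0)), "not reachable")
})
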