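thia <- guts_params("thiacloprid", "sd")
k_dec_thia <- sfo_rate_from_fraction(0.107)

test_that("stress and feeding inhibition follow the DEBtox forms", {
  tk <- tktd_params(k_d = 0.1, z_sub = 0.01, c_T = 0.02)
  expect_equal(stress_level(c(0, 0.005, 0.01), tk), c(0, 0, 0))
  expect_equal(stress_level(0.03, tk), 1)            # one tolerance above z
  expect_equal(stress_level(0.05, tk), 2)            # linear above threshold
  expect_equal(stress_level(0.01 + c(1, 2) * 0.004, tk), c(0.2, 0.4))

  expect_equal(effective_f(0.9, 0), 0.9)
  expect_equal(effective_f(0.9, 0.5), 0.45)
  expect_equal(effective_f(0.9, c(1, 1.7)), c(0, 0)) # complete inhibition
})

test_that("unexposed chronic runs reproduce the control exactly", {
  deb <- deb_params()
  tk <- tktd_params(thia$k_d, thia$z / 10, thia$z / 20)
  out <- simulate_chronic(0, k_dec_thia, thia$k_d, tk, deb)
  ctrl <- simulate_larva(deb)
  expect_equal(out$development_rate, ctrl$development_rate,
               tolerance = 1e-6)
  expect_equal(out$lethal_fraction, 0, tolerance = 1e-9)
})

test_that("saturated stress reduces to the fully starved run", {
  deb <- deb_params()
  tk <- tktd_params(thia$k_d, thia$z / 10, thia$z / 20)
  # concentration so high that s >= 1 throughout the test
  out <- simulate_chronic(1000 * thia$z, k_dec_thia, thia$k_d, tk, deb)
  expect_equal(out$lethal_fraction, 1)
  expect_equal(out$development_rate, 0)
  p0 <- deb; p0$f <- 0
  starved <- simulate_larva(p0)
  expect_equal(log(out$survival), log(starved$survival_to_emergence),
               tolerance = 0.15)
})

test_that("chronic outcomes are stable under solver refinement", {
  deb <- deb_params()
  tk <- tktd_params(thia$k_d, thia$z / 10, thia$z / 20)
  for (cc in c(0.002, 0.004, 0.008)) {
    coarse <- simulate_chronic(cc, k_dec_thia, thia$k_d, tk, deb)
    fine <- simulate_chronic(cc, k_dec_thia, thia$k_d, tk, deb,
                             rtol = 1e-9, atol = 1e-11)
    expect_equal(coarse$development_rate, fine$development_rate,
                 tolerance = 1e-4)
    expect_equal(coarse$lethal_fraction, fine$lethal_fraction,
                 tolerance = 1e-4)
  }
})

test_that("concentration response is monotone with a no-effect limit", {
  deb <- deb_params()
  tk <- tktd_params(thia$k_d, thia$z / 10, thia$z / 20)
  concs <- c(0, 0.001, 0.002, 0.004, 0.008, 0.016, 0.032)
  out <- purrr::map_dfr(concs, ~simulate_chronic(.x, k_dec_thia, thia$k_d,
                                                 tk, deb))
  expect_true(all(diff(out$lethal_fraction) >= -1e-9))
  expect_true(all(diff(out$development_rate) <= 1e-9))

  # threshold above the peak damage of the top concentration: all controls
  peak <- max(scaled_damage(exposure_sfo(max(concs), k_dec_thia),
                            thia$k_d, seq(0, 672, 4))$running_max)
  tk_hi <- tktd_params(thia$k_d, peak * 1.01, thia$z / 20)
  out_hi <- purrr::map_dfr(concs,
                           ~simulate_chronic(.x, k_dec_thia, thia$k_d,
                                             tk_hi, deb))
  ctrl <- simulate_larva(deb)
  expect_equal(out_hi$development_rate,
               rep(ctrl$development_rate, length(concs)), tolerance = 1e-6)
  expect_equal(out_hi$lethal_fraction, rep(0, length(concs)),
               tolerance = 1e-9)
})

test_that("the control feeding level is recovered by root finding", {
  deb <- deb_params()
  p8 <- deb; p8$f <- 0.8
  target <- simulate_larva(p8, horizon = 60)$development_rate
  f_hat <- adjust_control_f(target, deb, horizon = 60)
  expect_equal(f_hat, 0.8, tolerance = 1e-3)

  # development rate is monotone in f over the bracket
  rates <- vapply(c(0.8, 0.9, 1), function(f) {
    pf <- deb; pf$f <- f
    simulate_larva(pf, horizon = 60)$development_rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))

  # a rate faster than f = 1 allows is an explicit error
  expect_error(adjust_control_f(rates[3] + 0.01, deb, horizon = 60),
               "unattainable")
})

test_that("noise-free chronic data identify both toxicodynamic parameters", {
  deb <- deb_params()
  truth <- tktd_params(thia$k_d, thia$z / 10, 0.002)
  concs <- 10^seq(log10(0.0008), log10(0.02), length.out = 7)
  obs <- purrr::map_dfr(concs, ~simulate_chronic(.x, k_dec_thia, thia$k_d,
                                                 truth, deb))
  fit <- fit_debtktd(obs, thia$k_d, deb, k_dec_thia, n_starts = 6, seed = 1)
  expect_true(fit$identifiable)
  expect_equal(fit$params$z_sub, truth$z_sub, tolerance = 0.05)
  expect_equal(fit$params$c_T, truth$c_T, tolerance = 0.05)
})

test_that("effect-free chronic data are flagged unidentifiable", {
  deb <- deb_params()
  ctrl <- simulate_larva(deb)
  flat <- tibble::tibble(
    concentration = c(0.001, 0.002, 0.004, 0.008),
    development_rate = ctrl$development_rate,
    lethal_fraction = 0
  )
  fit <- fit_debtktd(flat, thia$k_d, deb, k_dec_thia, n_starts = 4,
                     seed = 2)
  expect_false(fit$identifiable)
})

test_that("parameters are recovered from noisy replicated chronic data", {
  deb <- deb_params()
  truth <- tktd_params(thia$k_d, thia$z / 10, 0.002)
  concs <- 10^seq(log10(0.001), log10(0.016), length.out = 6)
  base <- purrr::map_dfr(concs, ~simulate_chronic(.x, k_dec_thia, thia$k_d,
                                                  truth, deb))
  rel_err <- purrr::map_dfr(1:8, function(rep_i) {
    set.seed(100 + rep_i)
    noisy <- base
    noisy$development_rate <- base$development_rate *
      exp(stats::rnorm(nrow(base), 0, 0.1))
    noisy$lethal_fraction <- pmin(1, pmax(0, base$lethal_fraction *
      exp(stats::rnorm(nrow(base), 0, 0.1))))
    fit <- fit_debtktd(noisy[c("concentration", "development_rate",
                               "lethal_fraction")],
                       thia$k_d, deb, k_dec_thia, n_starts = 4,
                       seed = rep_i)
    tibble::tibble(z = abs(fit$params$z_sub - truth$z_sub) / truth$z_sub,
                   cT = abs(fit$params$c_T - truth$c_T) / truth$c_T)
  })
  expect_lte(stats::median(rel_err$z), 0.25)
  expect_lte(stats::median(rel_err$cT), 0.25)
})
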