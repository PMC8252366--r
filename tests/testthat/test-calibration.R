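test_that("censoring takes the running maximum and is idempotent", {
  d <- tibble::tibble(treatment = 1, time_h = c(6, 12, 24, 48), n0 = 5,
                      n_affected = c(0, 2, 1, 3))
  expect_equal(censor_immobility(d)$n_affected, c(0, 2, 2, 3))
  expect_equal(censor_immobility(censor_immobility(d))$n_affected,
               c(0, 2, 2, 3))

  d2 <- tibble::tibble(treatment = 1, time_h = c(6, 24, 48), n0 = 5,
                       n_affected = c(5, 0, 0))
  expect_equal(censor_immobility(d2)$n_affected, c(5, 5, 5))

  mono <- tibble::tibble(treatment = 1, time_h = c(6, 24, 48), n0 = 5,
                         n_affected = c(0, 1, 4))
  expect_equal(censor_immobility(mono)$n_affected, c(0, 1, 4))

  bad <- tibble::tibble(treatment = 1, time_h = 24, n0 = 5, n_affected = 6)
  expect_error(censor_immobility(bad), "n0")
})

test_that("the acute and chronic CSV readers round-trip their layouts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,replicate,conc_mg_L,time_h,n_start,n_affected",
               "thiacloprid,1,0.02,24,5,1", "thiacloprid,1,0.02,48,5,2",
               "thiacloprid,1,0,24,5,0", "thiacloprid,1,0,48,5,0"), f)
  d <- read_acute_csv(f)
  expect_equal(d$treatment, c(2, 2, 1, 1))
  expect_equal(d$n0, rep(5, 4))
  # the result is directly consumable by the likelihood (background
  # hazard > 0 so the recorded control and treatment deaths are possible)
  p <- guts_params_sd(0.1, 0.01, 0.05, 10)
  expect_true(is.finite(guts_loglik(p, d)))

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,conc0_mg_L,n_initial,n_emerged,emergence_day",
               "thiacloprid,0.004,20,12,16", "thiacloprid,0.004,20,10,17",
               "thiacloprid,0.008,20,0,NA"), g)
  ch <- read_chronic_csv(g)
  expect_equal(ch$replicate, c(1, 2, 1))
  expect_equal(ch$n_emerged, c(12, 10, 0))
})

test_that("conditional-binomial likelihood matches closed forms", {
  p <- guts_params_sd(k_d = 0.1, h_b = 0.005, z = 0.02, k_k = 5)

  # everyone survives: loglik telescopes to n0 * log S(t_end) per treatment
  d <- tibble::tibble(treatment = rep(1:2, each = 2),
                      conc = rep(c(0.05, 0.1), each = 2),
                      time_h = rep(c(24, 48), 2), n0 = 10, n_affected = 0)
  s_end <- vapply(c(0.05, 0.1), function(cc) {
    survival_sd(p, exposure_constant(cc), 48)$survival
  }, numeric(1))
  expect_equal(guts_loglik(p, d), sum(10 * log(s_end)), tolerance = 1e-10)

  # zero exposure, no background, no deaths: certain data
  p0 <- guts_params_sd(k_d = 0.1, h_b = 0, z = 0.02, k_k = 5)
  d0 <- tibble::tibble(treatment = 1, conc = 0, time_h = c(24, 48), n0 = 10,
                       n_affected = 0)
  expect_equal(guts_loglik(p0, d0), 0)

  # impossible data: survivors after survival hits zero
  p_kill <- guts_params_sd(k_d = 5, h_b = 0, z = 1e-4, k_k = 1e4)
  d_imp <- tibble::tibble(treatment = 1, conc = 10, time_h = c(24, 48),
                          n0 = 10, n_affected = c(0, 0))
  expect_identical(guts_loglik(p_kill, d_imp), -Inf)
})

test_that("likelihood equals the exhaustive multinomial path probability", {
  p <- guts_params_sd(k_d = 0.15, h_b = 0.003, z = 0.01, k_k = 20)
  d <- tibble::tibble(
    treatment = rep(1:2, each = 3),
    conc = rep(c(0.02, 0.05), each = 3),
    time_h = rep(c(12, 24, 48), 2), n0 = 5,
    n_affected = c(0, 1, 2, 1, 3, 5)
  )
  oracle <- sum(vapply(1:2, function(i) {
    g <- d[d$treatment == i, ]
    S <- survival_sd(p, exposure_constant(g$conc[1]), g$time_h)$survival
    multinomial_path_loglik(5, 5 - g$n_affected, S)
  }, numeric(1)))
  expect_equal(guts_loglik(p, d), oracle, tolerance = 1e-10)
})

test_that("loglik improves as predictions approach the generating truth", {
  truth <- guts_params("thiacloprid", "sd")
  des <- acute_design(c(0, 0.01, 0.02, 0.05, 0.1), n_per_group = 50,
                      obs_times = c(4, 8, 24, 48))
  dat <- gen_acute(truth, des, seed = 3)
  ll_at <- function(kd_factor) {
    p <- truth; p$k_d <- truth$k_d * kd_factor
    guts_loglik(p, dat)
  }
  lls <- vapply(c(0.2, 0.5, 1, 2, 5), ll_at, numeric(1))
  expect_true(which.max(lls) %in% c(3))
  expect_true(all(diff(lls[1:3]) > 0) && all(diff(lls[3:5]) < 0))
})

test_that("fit_guts is reproducible and flags unidentifiable thresholds", {
  truth <- guts_params_sd(0.1, 0, 0.05, 10)
  des <- acute_design(c(0, 0.02, 0.08, 0.2), n_per_group = 20,
                      obs_times = c(24, 48))
  dat <- gen_acute(truth, des, seed = 5)
  f1 <- fit_guts(dat, "sd", chains = 2, iter = 400, seed = 9)
  f2 <- fit_guts(dat, "sd", chains = 2, iter = 400, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_guts(dat, "sd", chains = 2, iter = 400, seed = 10)
  expect_false(identical(f1$draws, f3$draws))

  # no deaths anywhere: threshold runs into its prior bound and is flagged
  no_eff <- dat
  no_eff$n_affected <- 0
  f4 <- fit_guts(no_eff, "sd", chains = 2, iter = 600, seed = 1)
  expect_false(f4$threshold_identifiable)
})

test_that("SPPE and NRMSE follow their definitions", {
  # predicted final survival 0.6 vs observed 10/20: SPPE = -10%
  h_b <- -log(0.6) / 48
  p <- guts_params_sd(k_d = 0.1, h_b = h_b, z = 99, k_k = 0)
  d <- tibble::tibble(treatment = 1, conc = 0, time_h = 48, n0 = 20,
                      n_affected = 10)
  fit <- make_fixed_fit(p, d)
  expect_equal(sppe(fit)$sppe, -10, tolerance = 1e-9)

  # exact prediction: SPPE = 0, NRMSE = 0
  p0 <- guts_params_sd(k_d = 0.1, h_b = 0, z = 99, k_k = 0)
  d0 <- tibble::tibble(treatment = 1, conc = 0, time_h = c(24, 48), n0 = 20,
                       n_affected = 0)
  fit0 <- make_fixed_fit(p0, d0)
  expect_equal(sppe(fit0)$sppe, 0)
  expect_equal(nrmse(fit0), 0)

  # over-/under-prediction sign convention
  d_over <- tibble::tibble(treatment = 1, conc = 0, time_h = 48, n0 = 20,
                           n_affected = 4)  # observed 0.8 > predicted 0.6
  expect_gt(make_fixed_fit(p, d_over) |> sppe() |> (\(x) x$sppe)(), 0)

  # +1 offset on counts with observed mean 10: NRMSE = 10%
  hb2 <- 0.01
  t1 <- -log(0.6) / hb2; t2 <- -log(0.5) / hb2  # predictions 12 and 10
  p2 <- guts_params_sd(k_d = 0.1, h_b = hb2, z = 99, k_k = 0)
  d2 <- tibble::tibble(treatment = 1, conc = 0, time_h = c(t1, t2), n0 = 20,
                       n_affected = c(9, 11))  # observed 11 and 9
  expect_equal(nrmse(make_fixed_fit(p2, d2)), 10, tolerance = 1e-9)
})

test_that("PPC covers a degenerate dataset completely or not at all", {
  p <- guts_params_sd(k_d = 0.1, h_b = 0.005, z = 99, k_k = 0)
  d_in <- tibble::tibble(treatment = 1, conc = 0, time_h = 48, n0 = 20,
                         n_affected = 5)
  d_out <- tibble::tibble(treatment = 1, conc = 0, time_h = 48, n0 = 20,
                          n_affected = 20)
  expect_equal(ppc(make_fixed_fit(p, d_in)), 100)
  expect_equal(ppc(make_fixed_fit(p, d_out)), 0)
})

test_that("a mis-specified death mechanism loses predictive coverage", {
  # two identical pulses separate the mechanisms: under IT the second pulse
  # kills nobody new (thresholds already exceeded), under SD it does
  truth <- guts_params_sd(0.3, 0.001, 0.02, 8)
  des <- acute_design(c(0, 0.03, 0.06, 0.12, 0.25), n_per_group = 400,
                      obs_times = c(4, 8, 12, 24, 28, 32, 36, 48),
                      profile = "pulse8")
  dat <- gen_acute(truth, des, seed = 21)
  fit_true <- fit_guts(dat, "sd", chains = 3, iter = 1500, seed = 2)
  fit_mis <- fit_guts(dat, "it", chains = 3, iter = 1500, seed = 2)
  expect_gt(ppc(fit_true), ppc(fit_mis))
  expect_lt(nrmse(fit_true), nrmse(fit_mis))
})
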