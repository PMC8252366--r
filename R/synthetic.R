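# Seeded generators for acute and chronic datasets with the statistical
# structure the models assume.  The default designs mirror standard
# test-guideline geometry: acute water-only tests in groups of 5 for 48 h
# (constant or 4/8-h pulses on days 0 and 1), chronic 28-d spiked-water
# tests with 20 larvae per replicate and SFO-declining exposure.

#' Acute test design
#'
#' @param concentrations tested concentrations (mg/L); for pulse designs the
#'   concentration during the pulse.
#' @param n_per_group individuals per treatment group (default 5, the
#'   standard acute design).
#' @param obs_times observation times (h), default 24 and 48.
#' @param profile `"constant"` (48-h static), `"pulse4"` or `"pulse8"`
#'   (two pulses, days 0 and 1).
#' @param replicates replicates per concentration.
#' @return A list of class `acute_design`.
#' @export
acute_design <- function(concentrations, n_per_group = 5,
                         obs_times = c(24, 48),
                         profile = c("constant", "pulse4", "pulse8"),
                         replicates = 1) {
  profile <- match.arg(profile)
  stopifnot(all(concentrations >= 0), n_per_group >= 1,
            all(obs_times > 0), !is.unsorted(obs_times, strictly = TRUE))
  structure(list(concentrations = concentrations,
                 n_per_group = n_per_group, obs_times = obs_times,
                 profile = profile, replicates = replicates),
            class = "acute_design")
}

design_profile <- function(design, conc) {
  t_end <- max(design$obs_times, 48)
  switch(design$profile,
    constant = exposure_constant(conc, t_end = t_end),
    pulse4 = make_pulse_profile(conc, 4, c(0, 1), t_end = t_end),
    pulse8 = make_pulse_profile(conc, 8, c(0, 1), t_end = t_end)
  )
}

#' Generate a synthetic acute dataset from a known GUTS truth
#'
#' Under SD truth, interval deaths are drawn per individual from the
#' conditional-binomial implied by the model survival curve; under IT truth,
#' each individual receives a log-logistic threshold draw plus an
#' exponential background event time.  Optionally, individuals newly flagged
#' immobile revert to mobile at the following observation with probability
#' `recovery_prob`, producing the decreasing raw counts that the censoring
#' rule removes.  Generators are pure functions of (design, truth, seed).
#'
#' @param truth a [guts_params_sd()] or [guts_params_it()] object.
#' @param design an [acute_design()].
#' @param seed integer seed.
#' @param recovery_prob probability that a newly affected individual is
#'   recorded mobile again at the next observation (default 0).
#' @return A tibble with columns `treatment`, `replicate`, `conc`, `time_h`,
#'   `n0`, `n_affected`; for pulse designs an attribute `"profiles"` carries
#'   the per-treatment exposure profiles.
#' @export
gen_acute <- function(truth, design, seed = 1, recovery_prob = 0) {
  set.seed(seed)
  is_sd <- inherits(truth, "guts_params_sd")
  obs <- design$obs_times
  profiles <- list()
  rows <- list()
  for (ci in seq_along(design$concentrations)) {
    conc <- design$concentrations[ci]
    prof <- design_profile(design, conc)
    profiles[[as.character(ci)]] <- prof
    S <- guts_survival(truth, prof, obs)$survival
    for (rep in seq_len(design$replicates)) {
      n <- design$n_per_group
      if (is_sd) {
        # per-individual sequential Bernoulli survival (equals the
        # conditional binomial at the count level)
        alive <- rep(TRUE, n)
        first_affected <- rep(NA_integer_, n)
        S_prev <- 1
        for (i in seq_along(obs)) {
          p <- if (S_prev > 0) min(1, S[i] / S_prev) else 0
          dies <- alive & (stats::runif(n) > p)
          first_affected[dies] <- i
          alive <- alive & !dies
          S_prev <- S[i]
        }
      } else {
        u <- stats::runif(n)
        thr <- truth$alpha * (u / (1 - u))^(1 / truth$beta)
        bg <- if (truth$h_b > 0) stats::rexp(n, truth$h_b) else rep(Inf, n)
        mx <- running_max_at_times(prof, truth$k_d, obs)
        first_affected <- vapply(seq_len(n), function(j) {
          hit <- which(mx >= thr[j] | obs >= bg[j])
          if (length(hit)) hit[1] else NA_integer_
        }, integer(1))
      }
      # recorded status: optional one-observation recovery of newly
      # flagged individuals (raw counts may then decrease over time)
      recorded <- matrix(FALSE, n, length(obs))
      for (j in seq_len(n)) {
        fa <- first_affected[j]
        if (!is.na(fa)) {
          recorded[j, fa:length(obs)] <- TRUE
          if (recovery_prob > 0 && fa < length(obs) &&
              stats::runif(1) < recovery_prob) {
            recorded[j, fa + 1] <- FALSE
          }
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        treatment = ci, replicate = rep, conc = conc, time_h = obs,
        n0 = n, n_affected = colSums(recorded)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (design$profile != "constant") attr(out, "profiles") <- profiles
  out
}

#' Chronic test design
#'
#' @param concentrations initial water concentrations (mg/L), controls
#'   included as 0.
#' @param replicates replicates per concentration (default 8).
#' @param n_per_replicate larvae per replicate (default 20).
#' @param horizon test duration (d), default 28.
#' @return A list of class `chronic_design`.
#' @export
chronic_design <- function(concentrations, replicates = 8,
                           n_per_replicate = 20, horizon = 28) {
  stopifnot(all(concentrations >= 0), replicates >= 1, n_per_replicate >= 1)
  structure(list(concentrations = concentrations, replicates = replicates,
                 n_per_replicate = n_per_replicate, horizon = horizon),
            class = "chronic_design")
}

#' Generate a synthetic chronic dataset from DEB-TK-TD truth
#'
#' Per replicate, the number of emerging adults is drawn
#' Binomial(n, exp(-H)) where H is the cumulative starvation hazard at
#' pupation from [simulate_chronic()], with the deterministic emergence day
#' (optionally jittered by one day).
#'
#' @param design a [chronic_design()].
#' @param guts_kd dominant rate constant (1/h) fixed from the GUTS fit.
#' @param tktd a [tktd_params()] truth.
#' @param deb a [deb_params()] set (control feeding level already adjusted).
#' @param k_decline SFO water dissipation rate (1/h).
#' @param seed integer seed.
#' @param day_jitter if `TRUE`, emergence days are jittered by -1/0/+1 d per
#'   replicate.
#' @return A tibble with `concentration`, `replicate`, `n_initial`,
#'   `n_emerged`, `emergence_day` (NA where nothing emerged).
#' @export
gen_chronic <- function(design, guts_kd, tktd, deb, k_decline, seed = 1,
                        day_jitter = FALSE) {
  set.seed(seed)
  rows <- list()
  for (conc in design$concentrations) {
    out <- simulate_chronic(conc, k_decline, guts_kd, tktd, deb,
                            horizon = design$horizon)
    emerged_day <- out$emergence_time
    p_emerge <- if (is.na(emerged_day)) 0 else out$survival
    for (rep in seq_len(design$replicates)) {
      n_em <- stats::rbinom(1, design$n_per_replicate, p_emerge)
      day <- if (n_em > 0) {
        emerged_day + if (day_jitter) sample(-1:1, 1) else 0
      } else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        concentration = conc, replicate = rep,
        n_initial = design$n_per_replicate, n_emerged = n_em,
        emergence_day = day
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a noisy measured-concentration series
#'
#' Lognormal multiplicative noise (mean-unbiased, coefficient of variation
#' `cv`) around an SFO dissipation curve; emulates the sparse analytical
#' sampling of chronic tests (typically start, day 7 and termination).
#'
#' @param c0 initial concentration (mg/L).
#' @param k_decline SFO rate (1/h).
#' @param times_h sampling times (h).
#' @param cv coefficient of variation of the measurement noise; `cv = 0`
#'   returns the exact curve.
#' @param seed integer seed.
#' @return A tibble with `time_h` and `conc`, ready for [fit_sfo()].
#' @export
gen_measured_series <- function(c0, k_decline, times_h = c(0, 168, 672),
                                cv = 0.1, seed = 1) {
  set.seed(seed)
  true <- c0 * exp(-k_decline * times_h)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    true <- true * exp(stats::rnorm(length(true), -sdlog^2 / 2, sdlog))
  }
  tibble::tibble(time_h = times_h, conc = true)
}
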