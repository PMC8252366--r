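#' Toxicodynamic parameters of the DEB coupling
#'
#' The scaled damage driving sublethal stress uses the same first-order
#' kinetics (and, in the default pipeline, the same dominant rate constant)
#' as the stochastic-death GUTS model.  Only two parameters are estimated
#' from chronic data: the sublethal damage threshold `z_sub` and the
#' tolerance concentration `c_T` that scales stress per unit damage above
#' the threshold.
#'
#' @param k_d dominant rate constant (1/h), fixed from the GUTS-RED-SD fit
#'   and never re-estimated here.
#' @param z_sub sublethal damage threshold (mg/L).
#' @param c_T tolerance concentration (mg/L), positive.
#' @return A list of class `tktd_params`.
#' @export
tktd_params <- function(k_d, z_sub, c_T) {
  stopifnot(k_d > 0, z_sub >= 0, c_T > 0)
  structure(list(k_d = k_d, z_sub = z_sub, c_T = c_T),
            class = "tktd_params")
}

#' Stress level from scaled damage
#'
#' Linear-with-threshold stress, the DEBtox convention:
#' \eqn{s = \max(0, (D - z_{sub}) / c_T)}.
#'
#' @param D scaled damage (mg/L), vectorised.
#' @param params a [tktd_params()] object.
#' @return Dimensionless stress level(s), \eqn{\ge 0}.
#' @export
stress_level <- function(D, params) {
  pmax(0, (D - params$z_sub) / params$c_T)
}

#' Effective functional response under feeding inhibition
#'
#' The physiological mode of action is feeding inhibition: stress acts
#' multiplicatively on the scaled functional response,
#' \eqn{f_{eff} = f \max(0, 1 - s)}; complete inhibition at \eqn{s \ge 1}.
#'
#' @param f baseline scaled functional response.
#' @param s stress level from [stress_level()].
#' @return Effective functional response in `[0, f]`.
#' @export
effective_f <- function(f, s) {
  f * pmax(0, 1 - s)
}

#' Simulate a chronic test at one concentration
#'
#' Jointly integrates scaled damage (SFO-declining water exposure, rates
#' given per hour and converted internally to the DEB day timescale) and the
#' DEB state, with feeding inhibition as the physiological mode of action
#' and starvation as the only death mechanism (no background hazard).  The
#' chronic lethal fraction uses the emergence proxy: one minus the expected
#' fraction emerging, i.e. \eqn{1 - e^{-H}} for emerging cohorts and 1 when
#' nothing emerges within the horizon.
#'
#' @param c0 initial water concentration (mg/L).
#' @param k_decline SFO dissipation rate (1/h).
#' @param guts_kd dominant rate constant (1/h) from the GUTS-RED-SD fit.
#' @param tktd a [tktd_params()] object (its `k_d` is ignored in favour of
#'   `guts_kd` when both are supplied; they are the same quantity).
#' @param deb a [deb_params()] object with `f` already adjusted to the
#'   control development rate.
#' @param horizon test duration (d), default 28.
#' @param rtol,atol solver tolerances.
#' @return A one-row tibble (`chronic outcome`): `concentration`,
#'   `development_rate` (1/d), `lethal_fraction`, `emergence_time` (d, NA if
#'   none) and `survival` (to emergence).
#' @examples
#' p <- guts_params("thiacloprid", "sd")
#' tk <- tktd_params(p$k_d, z_sub = p$z / 10, c_T = p$z / 20)
#' simulate_chronic(0.01, sfo_rate_from_fraction(0.107), p$k_d, tk,
#'                  deb_params())
#' @export
simulate_chronic <- function(c0, k_decline, guts_kd = tktd$k_d, tktd, deb,
                             horizon = 28, rtol = 1e-8, atol = 1e-10) {
  stopifnot(c0 >= 0, k_decline >= 0)
  tox <- list(k_d_day = 24 * guts_kd, k_decline_day = 24 * k_decline,
              c0 = c0, z_sub = tktd$z_sub, c_T = tktd$c_T)
  res <- integrate_larva(deb, NULL, horizon, tox = tox,
                         rtol = rtol, atol = atol, grid_dt = horizon)
  sol <- res$sol
  pup <- res$pupation_time
  surv <- exp(-sol[nrow(sol), "H"])
  emergence <- if (!is.na(pup)) pup + deb$t_pupal else NA_real_
  emerged <- !is.na(emergence) && emergence <= horizon && surv >= 1e-6
  tibble::tibble(
    concentration = c0,
    development_rate = if (emerged) 1 / emergence else 0,
    lethal_fraction = if (emerged) 1 - unname(surv) else 1,
    emergence_time = if (emerged) emergence else NA_real_,
    survival = unname(surv)
  )
}

#' Adjust the control feeding level to an observed development rate
#'
#' One-dimensional root finding on the scaled functional response `f` such
#' that the simulated control development rate matches the observed one.
#' The rate is monotone increasing in `f`; an observed rate faster than the
#' model allows even at `f = 1` is an error.
#'
#' @param observed_rate observed control development rate (1/d).
#' @param deb a [deb_params()] object (its `f` is ignored).
#' @param horizon test duration (d).
#' @param tol tolerance on the development rate (1/d), default 1e-4.
#' @return The fitted `f`.
#' @export
adjust_control_f <- function(observed_rate, deb, horizon = 28, tol = 1e-4) {
  stopifnot(observed_rate > 0)
  rate_at <- function(f) {
    p <- deb; p$f <- f
    simulate_larva(p, horizon = horizon)$development_rate
  }
  if (rate_at(1) < observed_rate - tol) {
    stop("observed control development rate unattainable even at f = 1",
         call. = FALSE)
  }
  f_lo <- deb$L_p / deb$L_m + 1e-6  # below this the trigger is unreachable
  if (rate_at(f_lo) >= observed_rate) {
    stop("observed control development rate slower than the model floor",
         call. = FALSE)
  }
  stats::uniroot(function(f) rate_at(f) - observed_rate,
                 c(f_lo, 1), tol = 1e-6)$root
}

#' Read a chronic emergence dataset from CSV
#'
#' Expects replicate-level columns `compound`, `conc0_mg_L`, `n_initial`,
#' `n_emerged`, `emergence_day`; returns the layout consumed by
#' [fit_debtktd()].
#'
#' @param path CSV file path.
#' @return A tibble with `compound`, `concentration`, `replicate`,
#'   `n_initial`, `n_emerged`, `emergence_day`.
#' @export
read_chronic_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("compound", "conc0_mg_L", "n_initial", "n_emerged",
           "emergence_day")
  if (!all(req %in% names(d))) {
    stop("CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  replicate <- if ("replicate" %in% names(d)) d$replicate else
    stats::ave(seq_len(nrow(d)), d$compound, d$conc0_mg_L,
               FUN = seq_along)
  tibble::tibble(
    compound = d$compound, concentration = d$conc0_mg_L,
    replicate = replicate, n_initial = d$n_initial,
    n_emerged = d$n_emerged, emergence_day = d$emergence_day
  )
}

summarise_chronic <- function(data) {
  d <- tibble::as_tibble(data)
  if (all(c("development_rate", "lethal_fraction") %in% names(d)) &&
      !"n_emerged" %in% names(d)) {
    return(d |>
             dplyr::group_by(.data$concentration) |>
             dplyr::summarise(
               development_rate = mean(.data$development_rate),
               lethal_fraction = mean(.data$lethal_fraction),
               .groups = "drop"))
  }
  d |>
    dplyr::group_by(.data$concentration, .data$replicate) |>
    dplyr::summarise(
      development_rate = ifelse(sum(.data$n_emerged) > 0,
                                1 / mean(.data$emergence_day, na.rm = TRUE),
                                0),
      lethal_fraction = 1 - sum(.data$n_emerged) / sum(.data$n_initial),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(
      development_rate = mean(.data$development_rate),
      lethal_fraction = mean(.data$lethal_fraction),
      .groups = "drop"
    )
}

#' Calibrate the DEB-TK-TD model on chronic concentration-response data
#'
#' Estimates the two free toxicodynamic parameters (`z_sub`, `c_T`) on the
#' log10 scale by normalised least squares over the per-concentration mean
#' development rates and lethal fractions (each endpoint normalised by its
#' data mean; weights configurable), with seeded multi-start Nelder-Mead to
#' avoid local minima.  The dominant rate constant stays fixed at the
#' GUTS-derived value, and the control feeding level must have been adjusted
#' beforehand (see [adjust_control_f()]).
#'
#' @param data chronic data: either replicate-level (`concentration`,
#'   `replicate`, `n_initial`, `n_emerged`, `emergence_day`) or summarised
#'   (`concentration`, `development_rate`, `lethal_fraction`).  Controls
#'   (concentration 0) are excluded from the loss.
#' @param guts_kd dominant rate constant (1/h), fixed.
#' @param deb a [deb_params()] object with adjusted `f`.
#' @param k_decline SFO dissipation rate (1/h) of the chronic scenario.
#' @param weights length-2 numeric, relative weight of the development-rate
#'   and lethal-fraction endpoints.
#' @param n_starts number of seeded multi-starts (default 8).
#' @param seed integer seed for the start points.
#' @param horizon test duration (d).
#' @return An object of class `debtktd_fit`: `params` (a [tktd_params()]),
#'   `loss`, per-concentration `predictions`, an `identifiable` flag (FALSE
#'   when the data carry no treatment effect and the threshold runs to its
#'   upper bound) and the inputs.
#' @export
fit_debtktd <- function(data, guts_kd, deb, k_decline,
                        weights = c(1, 1), n_starts = 8, seed = 1,
                        horizon = 28) {
  obs <- summarise_chronic(data)
  obs <- obs[obs$concentration > 0, ]
  if (nrow(obs) < 2) stop("need at least two treated concentrations",
                          call. = FALSE)
  set.seed(seed)
  # damage scale of the tested range: peak damage at the top concentration
  peak <- max(running_max_at_times(
    exposure_sfo(max(obs$concentration), k_decline, t_end = 24 * horizon),
    guts_kd, 24 * horizon))
  lo <- log10(peak) - 3.5
  hi_z <- log10(peak) + 1
  hi_c <- log10(peak) + 1.5
  mean_rate <- mean(obs$development_rate)
  mean_lf <- mean(obs$lethal_fraction)
  flat_data <- mean_lf < 1e-6 && stats::sd(obs$development_rate) < 1e-8
  norm_rate <- max(mean_rate, 1e-6)
  norm_lf <- max(mean_lf, 0.05)

  predict_all <- function(z_sub, c_T) {
    tk <- tktd_params(guts_kd, z_sub, c_T)
    purrr::map_dfr(obs$concentration, function(cc) {
      simulate_chronic(cc, k_decline, guts_kd, tk, deb, horizon = horizon,
                       rtol = 1e-6, atol = 1e-8)
    })
  }
  loss_fn <- function(th) {
    if (th[1] < lo - 2 || th[1] > hi_z + 2 || th[2] < lo - 2 ||
        th[2] > hi_c + 2) return(1e10)
    pred <- predict_all(10^th[1], 10^th[2])
    sum(weights[1] * ((pred$development_rate - obs$development_rate) /
                        norm_rate)^2 +
        weights[2] * ((pred$lethal_fraction - obs$lethal_fraction) /
                        norm_lf)^2)
  }
  starts <- cbind(stats::runif(n_starts, lo, hi_z),
                  stats::runif(n_starts, lo, hi_c))
  fits <- lapply(seq_len(n_starts), function(i) {
    stats::optim(starts[i, ], loss_fn, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-8))
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  z_sub <- 10^best$par[1]; c_T <- 10^best$par[2]
  identifiable <- !flat_data && log10(z_sub) < hi_z - 0.05
  pred <- predict_all(z_sub, c_T)
  structure(list(
    params = tktd_params(guts_kd, z_sub, c_T),
    loss = best$value,
    predictions = dplyr::bind_cols(
      obs[, "concentration"],
      dplyr::rename(pred[, c("development_rate", "lethal_fraction")],
                    pred_development_rate = "development_rate",
                    pred_lethal_fraction = "lethal_fraction"),
      obs[, c("development_rate", "lethal_fraction")]
    ),
    identifiable = identifiable, observed = obs, deb = deb,
    guts_kd = guts_kd, k_decline = k_decline, weights = weights,
    seed = seed, horizon = horizon
  ), class = "debtktd_fit")
}

#' @export
print.debtktd_fit <- function(x, ...) {
  cat("DEB-TK-TD fit (feeding-inhibition PMoA, starvation mortality)\n")
  cat(sprintf("  z_sub = %.4g mg/L, c_T = %.4g mg/L (k_d fixed at %.4g 1/h)\n",
              x$params$z_sub, x$params$c_T, x$guts_kd))
  cat(sprintf("  loss = %.4g over %d concentrations\n", x$loss,
              nrow(x$observed)))
  if (!x$identifiable) cat("  warning: parameters not identifiable\n")
  invisible(x)
}

#' Tidy a DEB-TK-TD fit
#'
#' @param x a `debtktd_fit` object.
#' @param ... unused.
#' @return One row per estimated parameter.
#' @export
tidy.debtktd_fit <- function(x, ...) {
  tibble::tibble(term = c("z_sub", "c_T"),
                 estimate = c(x$params$z_sub, x$params$c_T))
}

#' @rdname tidy.debtktd_fit
#' @export
glance.debtktd_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, n_conc = nrow(x$observed),
                 identifiable = x$identifiable,
                 guts_kd = x$guts_kd, k_decline = x$k_decline)
}
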