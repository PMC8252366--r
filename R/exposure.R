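#' Exposure profiles
#'
#' An exposure profile describes the water concentration \eqn{C_w(t)} an
#' organism experiences over time as an ordered set of contiguous segments.
#' Within a segment starting at `t_start` the concentration is
#' \eqn{c_0 \exp(-k (t - t_{start}))}, so a segment with `k_decline = 0` is
#' constant and a segment with `k_decline > 0` dissipates with
#' single-first-order (SFO) kinetics.  All times are in hours, concentrations
#' in mg/L and rates in 1/h; inputs recorded in days are converted once at the
#' I/O boundary (see [read_measured_series()]).
#'
#' @param segments a data frame with columns `t_start`, `t_end` (h),
#'   `c0` (mg/L) and `k_decline` (1/h).  Segments must be contiguous,
#'   non-overlapping and in increasing time order.
#'
#' @return A tibble of segments with class `exposure_profile`.
#' @examples
#' prof <- exposure_sfo(c0 = 1, k_decline = 0.00333, t_end = 672)
#' conc_at(prof, c(0, 336, 672))
#' @export
exposure_profile <- function(segments) {
  seg <- tibble::as_tibble(segments)
  req <- c("t_start", "t_end", "c0", "k_decline")
  if (!all(req %in% names(seg))) {
    stop("segments must have columns t_start, t_end, c0, k_decline",
         call. = FALSE)
  }
  seg <- seg[req]
  if (nrow(seg) == 0) stop("profile needs at least one segment", call. = FALSE)
  if (any(seg$t_end <= seg$t_start)) {
    stop("each segment needs t_start < t_end", call. = FALSE)
  }
  if (any(seg$c0 < 0) || any(seg$k_decline < 0)) {
    stop("c0 and k_decline must be non-negative", call. = FALSE)
  }
  if (nrow(seg) > 1) {
    gaps <- seg$t_start[-1] - seg$t_end[-nrow(seg)]
    if (any(abs(gaps) > 1e-9)) {
      stop("segments must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  class(seg) <- c("exposure_profile", class(seg))
  seg
}

#' @rdname exposure_profile
#' @param conc constant concentration (mg/L).
#' @param t_end end of the profile domain (h).
#' @export
exposure_constant <- function(conc, t_end = 48) {
  exposure_profile(tibble::tibble(
    t_start = 0, t_end = t_end, c0 = conc, k_decline = 0
  ))
}

#' @rdname exposure_profile
#' @param c0 initial concentration of the declining segment (mg/L).
#' @param k_decline SFO dissipation rate (1/h).
#' @export
exposure_sfo <- function(c0, k_decline, t_end = 672) {
  exposure_profile(tibble::tibble(
    t_start = 0, t_end = t_end, c0 = c0, k_decline = k_decline
  ))
}

#' Pulsed exposure profile
#'
#' Builds the water-only pulsed design used in acute testing: square
#' concentration pulses starting at the beginning of the listed days, with
#' instantaneous transfer to clean medium at pulse end.
#'
#' @param pulse_conc concentration during the pulses (mg/L).
#' @param pulse_hours pulse duration (h); 4 and 8 h mirror the standard
#'   time-variable acute design.
#' @param pulse_days integer days on which a pulse starts (day 0 = t 0 h).
#' @param t_end profile end (h), default 48.
#' @return An [exposure_profile()].
#' @examples
#' make_pulse_profile(1, 4, c(0, 1))
#' @export
make_pulse_profile <- function(pulse_conc, pulse_hours, pulse_days = c(0, 1),
                               t_end = 48) {
  if (pulse_hours <= 0) stop("pulse_hours must be positive", call. = FALSE)
  starts <- sort(24 * pulse_days)
  ends <- starts + pulse_hours
  if (any(ends[-length(ends)] > starts[-1])) {
    stop("pulses overlap", call. = FALSE)
  }
  if (max(ends) > t_end) stop("pulse extends beyond t_end", call. = FALSE)
  bounds <- sort(unique(c(0, starts, ends, t_end)))
  seg <- tibble::tibble(
    t_start = bounds[-length(bounds)],
    t_end = bounds[-1]
  )
  in_pulse <- vapply(
    seg$t_start,
    function(t0) any(t0 >= starts - 1e-12 & t0 < ends - 1e-12),
    logical(1)
  )
  seg$c0 <- ifelse(in_pulse, pulse_conc, 0)
  seg$k_decline <- 0
  exposure_profile(seg)
}

#' Concentration at given times
#'
#' @param profile an [exposure_profile()].
#' @param t times (h) within the profile domain.
#' @return Numeric vector of concentrations (mg/L); continuous from the right
#'   at segment boundaries.
#' @export
conc_at <- function(profile, t) {
  seg <- profile
  t0 <- min(seg$t_start)
  t1 <- max(seg$t_end)
  if (any(t < t0 - 1e-9) || any(t > t1 + 1e-9)) {
    stop("time outside profile domain", call. = FALSE)
  }
  idx <- findInterval(pmin(pmax(t, t0), t1), seg$t_start,
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  seg$c0[idx] * exp(-seg$k_decline[idx] * (t - seg$t_start[idx]))
}

profile_end <- function(profile) max(profile$t_end)

#' Scale a profile's concentrations by a multiplier
#' @noRd
scale_profile <- function(profile, mult) {
  seg <- profile
  seg$c0 <- seg$c0 * mult
  seg
}

#' Fit single-first-order dissipation to measured concentrations
#'
#' Ordinary least squares on log-concentration versus time, the standard
#' procedure for sparse dissipation series (typically three measurements per
#' chronic test).
#'
#' @param data a data frame with columns `time_h` and `conc` (mg/L); at least
#'   two rows, all concentrations positive, times strictly increasing.
#' @return A one-row tibble with `k_decline` (1/h), `c0` (mg/L, fitted
#'   intercept) and `n` (points used).
#' @examples
#' ser <- tibble::tibble(time_h = c(0, 672), conc = c(1, 0.107))
#' fit_sfo(ser)
#' @export
fit_sfo <- function(data) {
  d <- tibble::as_tibble(data)
  if (!all(c("time_h", "conc") %in% names(d))) {
    stop("data must have columns time_h and conc", call. = FALSE)
  }
  if (nrow(d) < 2) stop("need at least two measurements", call. = FALSE)
  if (any(d$conc <= 0)) {
    stop("log-linear SFO fit requires positive concentrations", call. = FALSE)
  }
  if (any(diff(d$time_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(log(conc) ~ time_h, data = d)
  co <- stats::coef(fit)
  tibble::tibble(
    k_decline = max(0, -unname(co["time_h"])),
    c0 = exp(unname(co["(Intercept)"])),
    n = nrow(d)
  )
}

#' SFO rate from the fraction remaining after a duration
#'
#' Convenience inversion \eqn{k = -\ln(\mathrm{frac}) / t}; e.g. the rate
#' implied by the mean measured/nominal fraction at chronic test termination.
#'
#' @param frac fraction of the initial concentration remaining (0–1].
#' @param duration_h elapsed time (h), default 672 (28 d).
#' @return Rate in 1/h.
#' @export
sfo_rate_from_fraction <- function(frac, duration_h = 672) {
  stopifnot(frac > 0, frac <= 1, duration_h > 0)
  -log(frac) / duration_h
}

#' Read a measured dissipation series from CSV
#'
#' Expects columns `time_d`, `conc_mg_L` and optionally `nominal_mg_L`; days
#' are converted to hours on read so that everything downstream works in
#' hours.
#'
#' @param path CSV file path.
#' @return A tibble with `time_h`, `conc` and (if present) `nominal`.
#' @export
read_measured_series <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_d", "conc_mg_L") %in% names(d))) {
    stop("CSV must have columns time_d and conc_mg_L", call. = FALSE)
  }
  out <- tibble::tibble(time_h = 24 * d$time_d, conc = d$conc_mg_L)
  if ("nominal_mg_L" %in% names(d)) out$nominal <- d$nominal_mg_L
  out
}
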