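#' Plot GUTS survival curves over an exposure profile
#'
#' @param params a GUTS parameter object.
#' @param profile an [exposure_profile()].
#' @param times evaluation times (h); defaults to a fine grid over the
#'   profile domain.
#' @return A ggplot.
#' @export
plot_guts_survival <- function(params, profile, times = NULL) {
  if (is.null(times)) {
    times <- seq(0, profile_end(profile), length.out = 200)
  }
  d <- guts_survival(params, profile, times)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "survival probability") +
    ggplot2::ylim(0, 1)
}

#' @export
autoplot.guts_fit <- function(object, ...) {
  pn <- param_names(object$model)
  long <- tidyr::pivot_longer(object$draws, dplyr::all_of(pn),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = paste0("GUTS-RED-", toupper(object$model),
                                 " posterior marginals"))
}

#' @export
autoplot.chronic_prediction <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$concentration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial concentration (mg/L)",
                  y = "28-d lethal fraction")
  if (!is.null(data)) {
    obs <- summarise_chronic(data)
    p <- p + ggplot2::geom_point(
      data = obs[obs$concentration > 0, ],
      ggplot2::aes(.data$concentration, .data$lethal_fraction))
  }
  p
}

#' @export
autoplot.debtktd_fit <- function(object, n_grid = 40, ...) {
  grid <- 10^seq(log10(min(object$observed$concentration) / 3),
                 log10(max(object$observed$concentration) * 2),
                 length.out = n_grid)
  curve <- purrr::map_dfr(grid, function(cc) {
    simulate_chronic(cc, object$k_decline, object$guts_kd, object$params,
                     object$deb, horizon = object$horizon,
                     rtol = 1e-6, atol = 1e-8)
  })
  long_c <- tidyr::pivot_longer(
    curve[c("concentration", "development_rate", "lethal_fraction")],
    -"concentration", names_to = "endpoint", values_to = "value")
  long_o <- tidyr::pivot_longer(
    object$observed, -"concentration", names_to = "endpoint",
    values_to = "value")
  ggplot2::ggplot(long_c, ggplot2::aes(.data$concentration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = long_o) +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial concentration (mg/L)", y = NULL)
}
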