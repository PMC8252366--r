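#' Censor immobility counts to their running maximum
#'
#' GUTS does not allow the number of affected individuals to decrease over
#' time, but organisms can recover from immobility between observations of a
#' pulsed acute test.  Prior to calibration the affected counts are therefore
#' replaced by their cumulative maximum since the start of the experiment,
#' per treatment and replicate.  The operation is idempotent.
#'
#' @param data a tibble with columns `treatment`, `time_h`, `n0`,
#'   `n_affected` and optionally `replicate`.
#' @return The same tibble with `n_affected` censored (non-decreasing in
#'   time within each treatment/replicate).
#' @examples
#' d <- tibble::tibble(treatment = 1, time_h = c(6, 12, 24, 48),
#'                     n0 = 5, n_affected = c(0, 2, 1, 3))
#' censor_immobility(d)$n_affected  # 0 2 2 3
#' @export
censor_immobility <- function(data) {
  d <- tibble::as_tibble(data)
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  if (any(d$n_affected > d$n0) || any(d$n_affected < 0)) {
    stop("n_affected must lie in [0, n0]", call. = FALSE)
  }
  profs <- attr(data, "profiles")
  d <- d |>
    dplyr::arrange(.data$treatment, .data$replicate, .data$time_h) |>
    dplyr::group_by(.data$treatment, .data$replicate) |>
    dplyr::mutate(n_affected = cummax(.data$n_affected)) |>
    dplyr::ungroup()
  attr(d, "profiles") <- profs
  d
}

#' Read an acute survival dataset from CSV
#'
#' Expects columns `compound`, `replicate`, `conc_mg_L`, `time_h`,
#' `n_start`, `n_affected` (a `treatment` column is honoured if present,
#' otherwise treatments are numbered by unique concentration).  Returns the
#' tibble layout used by [fit_guts()].
#'
#' @param path CSV file path.
#' @return A tibble with `treatment`, `replicate`, `conc`, `time_h`, `n0`,
#'   `n_affected` and a `compound` column.
#' @export
read_acute_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("compound", "replicate", "conc_mg_L", "time_h", "n_start",
           "n_affected")
  if (!all(req %in% names(d))) {
    stop("CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  treatment <- if ("treatment" %in% names(d)) d$treatment else
    match(d$conc_mg_L, sort(unique(d$conc_mg_L)))
  tibble::tibble(
    compound = d$compound, treatment = treatment, replicate = d$replicate,
    conc = d$conc_mg_L, time_h = d$time_h, n0 = d$n_start,
    n_affected = d$n_affected
  )
}

# ---- internal dataset representation -------------------------------------

# One group per treatment x replicate: observation times, censored survivor
# counts, initial count and exposure profile.  Constant single-segment
# profiles get a fast closed-form survival path.
build_groups <- function(data) {
  d <- censor_immobility(data)
  profs <- attr(data, "profiles")
  keys <- unique(d[c("treatment", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    g <- d[d$treatment == keys$treatment[i] &
             d$replicate == keys$replicate[i], ]
    if (is.unsorted(g$time_h, strictly = TRUE)) {
      stop("observation times must be strictly increasing", call. = FALSE)
    }
    n0 <- g$n0[1]
    prof <- if (!is.null(profs)) profs[[as.character(g$treatment[1])]]
    if (is.null(prof)) {
      if (!"conc" %in% names(g) || is.na(g$conc[1])) {
        stop("treatment ", g$treatment[1],
             " has neither a conc column nor a profile", call. = FALSE)
      }
      prof <- exposure_constant(g$conc[1], t_end = max(g$time_h))
    }
    constant <- nrow(prof) == 1 && prof$k_decline[1] == 0
    list(times = g$time_h, surv = n0 - g$n_affected, n0 = n0,
         profile = prof, conc = if (constant) prof$c0[1] else NA_real_,
         constant = constant, treatment = g$treatment[1],
         replicate = g$replicate[1])
  })
}

# closed-form SD survival under constant exposure (hot path of the MCMC)
surv_sd_const <- function(conc, times, k_d, h_b, z, k_k) {
  H <- numeric(length(times))
  if (conc > z) {
    t_z <- if (z > 0) -log(1 - z / conc) / k_d else 0
    ab <- times > t_z
    t_ab <- times[ab]
    H[ab] <- (conc - z) * (t_ab - t_z) +
      (conc / k_d) * (exp(-k_d * t_ab) - exp(-k_d * t_z))
  }
  exp(-(h_b * times + k_k * H))
}

surv_it_const <- function(conc, times, k_d, h_b, alpha, beta) {
  mx <- conc * (1 - exp(-k_d * times))
  (1 - loglogistic_cdf(mx, alpha, beta)) * exp(-h_b * times)
}

group_survival <- function(g, params) {
  sd_model <- inherits(params, "guts_params_sd")
  if (g$constant) {
    if (sd_model) {
      surv_sd_const(g$conc, g$times, params$k_d, params$h_b, params$z,
                    params$k_k)
    } else {
      surv_it_const(g$conc, g$times, params$k_d, params$h_b, params$alpha,
                    params$beta)
    }
  } else {
    guts_survival(params, g$profile, g$times)$survival
  }
}

# conditional-binomial log-likelihood over all groups
loglik_groups <- function(params, groups) {
  ll <- 0
  for (g in groups) {
    S <- group_survival(g, params)
    S_prev <- c(1, S[-length(S)])
    n_prev <- c(g$n0, g$surv[-length(g$surv)])
    p <- ifelse(S_prev > 0, pmin(1, S / S_prev), 0)
    bad <- p == 0 & g$surv > 0
    if (any(bad)) return(-Inf)
    ll <- ll + sum(stats::dbinom(g$surv, n_prev, p, log = TRUE))
  }
  ll
}

#' Conditional-binomial log-likelihood of a GUTS model
#'
#' Survivor counts are modelled per observation interval as
#' \eqn{N_i \sim \mathrm{Binomial}(N_{i-1}, S(t_i)/S(t_{i-1}))}, summed over
#' treatments and replicates.  Data are censored with [censor_immobility()]
#' first.  Returns `-Inf` (not an error) for impossible data, i.e. survivors
#' observed after the model assigns zero survival probability.
#'
#' @param params a GUTS parameter object.
#' @inheritParams fit_guts
#' @return The log-likelihood (scalar).
#' @export
guts_loglik <- function(params, data) {
  loglik_groups(params, build_groups(data))
}

# ---- priors and parameter transforms -------------------------------------

# sampling scale: log10 for all rate/threshold parameters, natural for h_b
param_names <- function(model) {
  if (model == "sd") c("k_d", "z", "k_k", "h_b") else
    c("k_d", "alpha", "beta", "h_b")
}

theta_to_params <- function(theta, model) {
  if (model == "sd") {
    guts_params_sd(10^theta[1], theta[4], 10^theta[2], 10^theta[3])
  } else {
    guts_params_it(10^theta[1], theta[4], 10^theta[2], 10^theta[3])
  }
}

#' Default priors for GUTS calibration
#'
#' Log-uniform priors over wide, data-driven bounds: the threshold (`z` or
#' `alpha`) is bounded by the tested concentration range, the dominant rate
#' by the temporal resolution of the design, and the background hazard is
#' uniform on a range generously covering control mortality.
#'
#' @param data acute dataset (see [fit_guts()]).
#' @param model `"sd"` or `"it"`.
#' @return A list with `lower` and `upper` named vectors on the sampling
#'   scale (log10 except `h_b`).
#' @export
guts_default_priors <- function(data, model = c("sd", "it")) {
  model <- match.arg(model)
  groups <- build_groups(data)
  concs <- vapply(groups, function(g) max(conc_at(g$profile,
    seq(min(g$profile$t_start), max(g$profile$t_end), length.out = 50))),
    numeric(1))
  cpos <- concs[concs > 0]
  if (length(cpos) == 0) cpos <- 1
  t_max <- max(vapply(groups, function(g) max(g$times), numeric(1)))
  thr <- c(log10(min(cpos) / 20), log10(max(cpos) * 5))
  kd <- c(log10(-log(0.999) / t_max), log10(200 / t_max))
  if (model == "sd") {
    lower <- c(k_d = kd[1], z = thr[1], k_k = -4, h_b = 0)
    upper <- c(k_d = kd[2], z = thr[2], k_k = 5, h_b = 0.1)
  } else {
    lower <- c(k_d = kd[1], alpha = thr[1], beta = log10(0.2), h_b = 0)
    upper <- c(k_d = kd[2], alpha = thr[2], beta = log10(60), h_b = 0.1)
  }
  list(lower = lower, upper = upper)
}

log_posterior <- function(theta, groups, model, priors) {
  if (any(theta < priors$lower) || any(theta > priors$upper)) return(-Inf)
  loglik_groups(theta_to_params(theta, model), groups)
}

# split-chain potential scale reduction factor
split_rhat <- function(mat_list) {
  halves <- list()
  for (m in mat_list) {
    n <- nrow(m)
    halves <- c(halves, list(m[seq_len(n %/% 2), , drop = FALSE],
                             m[(n %/% 2 + 1):n, , drop = FALSE]))
  }
  vapply(seq_len(ncol(mat_list[[1]])), function(j) {
    chains <- lapply(halves, function(h) h[, j])
    n <- length(chains[[1]]); m <- length(chains)
    means <- vapply(chains, mean, numeric(1))
    vars <- vapply(chains, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Fit a GUTS-RED model to acute survival data by MCMC
#'
#' Bayesian calibration of the SD or IT model on (censored) immobility
#' counts with the conditional-binomial likelihood, log-uniform priors and
#' an adaptive random-walk Metropolis sampler (Haario-type covariance
#' adaptation during burn-in, frozen afterwards).  Chains are initialised
#' around a multi-start posterior mode.  Sampling is on the log10 scale for
#' all parameters except the background hazard.  Results are fully
#' reproducible given `seed`.
#'
#' @param data a tibble with columns `treatment`, `time_h`, `n0`,
#'   `n_affected`, optionally `replicate` and `conc` (constant exposure); an
#'   attribute `"profiles"` (named list of [exposure_profile()] keyed by
#'   treatment) overrides `conc` for time-variable designs.  Replicates with
#'   identical profiles are pooled at the likelihood level.
#' @param model `"sd"` or `"it"`.
#' @param priors optional list with `lower`/`upper` named vectors on the
#'   sampling scale; defaults to [guts_default_priors()].
#' @param chains number of chains (default 4; at least 3 recommended for
#'   convergence diagnostics).
#' @param iter iterations per chain (default 5000); the first half is
#'   discarded as burn-in.
#' @param seed integer seed.
#' @return An object of class `guts_fit` with posterior `draws` (tibble on
#'   the natural scale), `summary` (medians and 95% credible intervals),
#'   `rhat`, and a `converged` flag (all split-R-hat at or below 1.05).  If the
#'   threshold posterior piles up at its upper prior bound (no effects in
#'   the data) the fit is flagged `threshold_identifiable = FALSE`.
#' @seealso [tidy.guts_fit()], [ppc()], [nrmse()], [sppe()]
#' @export
fit_guts <- function(data, model = c("sd", "it"), priors = NULL,
                     chains = 4, iter = 5000, seed = 1) {
  model <- match.arg(model)
  groups <- build_groups(data)
  if (is.null(priors)) priors <- guts_default_priors(data, model)
  pn <- param_names(model)
  d <- length(pn)
  set.seed(seed)

  lp <- function(theta) log_posterior(theta, groups, model, priors)
  rng <- priors$upper - priors$lower

  # multi-start mode search to seed the chains; Nelder-Mead is restarted
  # from its own optimum because it is prone to premature collapse in 4-d
  starts <- c(
    list((priors$lower + priors$upper) / 2),
    lapply(seq_len(11), function(i) priors$lower + stats::runif(d) * rng)
  )
  obj <- function(th) {
    v <- lp(th)
    if (!is.finite(v)) 1e10 else -v
  }
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 500))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  polished <- lapply(fits[order(vals)[1:3]], function(f) {
    stats::optim(f$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 500))
  })
  pvals <- vapply(polished, function(f) f$value, numeric(1))
  map <- polished[[which.min(pvals)]]$par

  burn <- iter %/% 2
  keep_mats <- vector("list", chains)
  eps <- diag(1e-8, d)
  init_sd <- c(rep(0.1, d - 1), 0.02 * rng[d])  # log10 units; h_b natural
  for (ch in seq_len(chains)) {
    theta <- pmin(pmax(map + stats::rnorm(d, 0, init_sd),
                       priors$lower), priors$upper)
    cur_lp <- lp(theta)
    scale <- 1
    cov_base <- diag((0.05 * pmax(rng, 1e-3))^2)
    chol_prop <- chol(cov_base)
    hist_mat <- matrix(NA_real_, iter, d)
    acc <- 0L
    wide_sd <- c(rep(0.4, d - 1), 0.005)  # escape kernel, log10 units
    for (i in seq_len(iter)) {
      # symmetric mixture proposal: adapted kernel with an occasional wide
      # component so chains can leave secondary modes
      prop <- if (stats::runif(1) < 0.05) {
        theta + stats::rnorm(d, 0, wide_sd)
      } else {
        theta + scale * drop(stats::rnorm(d) %*% chol_prop)
      }
      prop_lp <- lp(prop)
      if (is.finite(prop_lp) &&
          log(stats::runif(1)) < prop_lp - cur_lp) {
        theta <- prop; cur_lp <- prop_lp; acc <- acc + 1L
      }
      hist_mat[i, ] <- theta
      if (i %% 50 == 0) {
        # Haario-type adaptation: proposal covariance tracks the whole
        # chain history (diminishing adaptation), the global scale is tuned
        # towards the multivariate optimum acceptance rate during burn-in
        if (i >= 100) {
          cov_emp <- stats::cov(hist_mat[seq_len(i), , drop = FALSE])
          ch_try <- tryCatch(chol(2.38^2 / d * cov_emp + eps),
                             error = function(e) NULL)
          if (!is.null(ch_try)) chol_prop <- ch_try
        }
        if (i <= burn) {
          rate <- acc / 50
          scale <- max(0.05, min(20, scale * exp(0.6 * (rate - 0.25))))
        }
        acc <- 0L
      }
    }
    keep_mats[[ch]] <- hist_mat[(burn + 1):iter, , drop = FALSE]
  }

  rhat <- split_rhat(keep_mats)
  names(rhat) <- pn

  natural <- function(m) {
    out <- m
    out[, 1:3] <- 10^m[, 1:3]
    out
  }
  draws <- dplyr::bind_rows(lapply(seq_len(chains), function(ch) {
    m <- natural(keep_mats[[ch]])
    colnames(m) <- pn
    dplyr::mutate(tibble::as_tibble(m), chain = ch,
                  iteration = seq_len(nrow(m)), .before = 1)
  }))

  qs <- apply(as.matrix(draws[pn]), 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975))
  summary_tbl <- tibble::tibble(
    term = pn,
    estimate = qs[1, ],
    conf.low = qs[2, ],
    conf.high = qs[3, ]
  )

  # when the data carry no effect information the threshold posterior is
  # essentially the prior: it either runs into the upper bound or stays
  # prior-wide.  Flag both.
  thr_name <- if (model == "sd") "z" else "alpha"
  thr_row <- summary_tbl[summary_tbl$term == thr_name, ]
  thr_hi <- priors$upper[thr_name]
  thr_range <- thr_hi - priors$lower[thr_name]
  at_bound <- (thr_hi - log10(thr_row$conf.high)) < 0.02 * thr_range
  prior_wide <- (log10(thr_row$conf.high) - log10(thr_row$conf.low)) >
    0.5 * thr_range
  threshold_identifiable <- !(at_bound || prior_wide)

  structure(list(
    model = model, draws = draws, summary = summary_tbl, rhat = rhat,
    converged = all(rhat <= 1.05), priors = priors, map = map,
    threshold_identifiable = threshold_identifiable,
    groups = groups, data = data, chains = chains, iter = iter, seed = seed
  ), class = "guts_fit")
}

#' @export
print.guts_fit <- function(x, ...) {
  cat("GUTS-RED-", toupper(x$model), " fit (", x$chains, " chains x ",
      x$iter, " iterations)\n", sep = "")
  print(x$summary)
  cat("max split-Rhat:", round(max(x$rhat), 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!x$threshold_identifiable) {
    cat("warning: threshold not identifiable (posterior at upper bound)\n")
  }
  invisible(x)
}

median_params <- function(fit) {
  est <- as.list(stats::setNames(fit$summary$estimate, fit$summary$term))
  if (fit$model == "sd") {
    guts_params_sd(est$k_d, est$h_b, est$z, est$k_k)
  } else {
    guts_params_it(est$k_d, est$h_b, est$alpha, est$beta)
  }
}

draw_params <- function(fit, i) {
  row <- fit$draws[i, ]
  if (fit$model == "sd") {
    guts_params_sd(row$k_d, row$h_b, row$z, row$k_k)
  } else {
    guts_params_it(row$k_d, row$h_b, row$alpha, row$beta)
  }
}

# ---- EFSA model performance criteria -------------------------------------

#' Posterior predictive check (PPC)
#'
#' For every observation, the 95% interval of predicted survivor counts is
#' computed by propagating posterior parameter draws through the
#' conditional-binomial observation model (conditioning on the previously
#' observed count); returns the percentage of observations covered by their
#' interval.
#'
#' @param fit a [fit_guts()] result.
#' @param data optional validation dataset; defaults to the calibration data.
#' @param n_draws posterior draws used (default 500).
#' @return Coverage in percent.
#' @export
ppc <- function(fit, data = NULL, n_draws = 500) {
  groups <- if (is.null(data)) fit$groups else build_groups(data)
  set.seed(fit$seed + 1000003L)
  idx <- sample.int(nrow(fit$draws), min(n_draws, nrow(fit$draws)))
  inside <- integer(0)
  for (g in groups) {
    n_prev <- c(g$n0, g$surv[-length(g$surv)])
    sims <- matrix(NA_integer_, length(idx), length(g$times))
    for (r in seq_along(idx)) {
      params <- draw_params(fit, idx[r])
      S <- group_survival(g, params)
      S_prev <- c(1, S[-length(S)])
      p <- ifelse(S_prev > 0, pmin(1, S / S_prev), 0)
      sims[r, ] <- stats::rbinom(length(p), n_prev, p)
    }
    lo <- apply(sims, 2, stats::quantile, 0.025)
    hi <- apply(sims, 2, stats::quantile, 0.975)
    inside <- c(inside, as.integer(g$surv >= lo & g$surv <= hi))
  }
  100 * mean(inside)
}

#' Normalised root mean square error (NRMSE)
#'
#' RMSE of posterior-median predicted versus observed survivor counts,
#' normalised by the mean observed count, in percent.
#'
#' @inheritParams ppc
#' @return NRMSE in percent.
#' @export
nrmse <- function(fit, data = NULL) {
  groups <- if (is.null(data)) fit$groups else build_groups(data)
  params <- median_params(fit)
  obs <- pred <- numeric(0)
  for (g in groups) {
    S <- group_survival(g, params)
    obs <- c(obs, g$surv)
    pred <- c(pred, g$n0 * S)
  }
  100 * sqrt(mean((pred - obs)^2)) / mean(obs)
}

#' Survival probability prediction error (SPPE)
#'
#' Per treatment/replicate: observed minus posterior-median predicted
#' survival fraction at the final observation time, in percentage points.
#' Positive values mean the model under-predicts survival (over-predicts the
#' effect).
#'
#' @inheritParams ppc
#' @return A tibble with `treatment`, `replicate` and `sppe` (percent).
#' @export
sppe <- function(fit, data = NULL) {
  groups <- if (is.null(data)) fit$groups else build_groups(data)
  params <- median_params(fit)
  purrr::map_dfr(groups, function(g) {
    S <- group_survival(g, params)
    last <- length(g$times)
    tibble::tibble(
      treatment = g$treatment, replicate = g$replicate,
      sppe = 100 * (g$surv[last] / g$n0 - S[last])
    )
  })
}

# ---- broom-style methods --------------------------------------------------

#' Tidy a GUTS fit
#'
#' @param x a `guts_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: posterior median
#'   (`estimate`), 95% credible interval and split-R-hat.
#' @export
tidy.guts_fit <- function(x, ...) {
  dplyr::mutate(x$summary, rhat = unname(x$rhat[x$summary$term]))
}

#' @rdname tidy.guts_fit
#' @export
glance.guts_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_obs = sum(vapply(x$groups, function(g) length(g$times), integer(1))),
    logLik = loglik_groups(median_params(x), x$groups),
    rhat_max = max(x$rhat),
    converged = x$converged,
    threshold_identifiable = x$threshold_identifiable
  )
}
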