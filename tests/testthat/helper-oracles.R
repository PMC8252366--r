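# Independent numerical oracles used across test files.  These deliberately
# avoid the package's analytic damage/hazard machinery: damage is built up
# by dense forward-Euler steps on the exposure function, hazards by
# rectangle sums, so they can serve as cross-checks of the closed forms.

euler_damage <- function(profile, k_d, t_end, dt = 0.001) {
  tt <- seq(0, t_end, by = dt)
  D <- numeric(length(tt))
  cw <- conc_at(profile, tt)
  for (i in 2:length(tt)) {
    D[i] <- D[i - 1] + k_d * (cw[i - 1] - D[i - 1]) * dt
  }
  list(times = tt, damage = D)
}

euler_survival_sd <- function(params, profile, times, dt = 0.001) {
  ed <- euler_damage(profile, params$k_d, max(times), dt)
  haz <- params$k_k * pmax(0, ed$damage - params$z) + params$h_b
  H <- c(0, cumsum(haz[-length(haz)]) * dt)
  exp(-H[match(round(times / dt), round(ed$times / dt))])
}

# Monte-Carlo survival oracles: SD by event-time sampling from the
# cumulative hazard, IT by per-individual threshold + background draws.
mc_survival_sd <- function(params, profile, times, n, dt = 0.01) {
  ed <- euler_damage(profile, params$k_d, max(times), dt)
  haz <- params$k_k * pmax(0, ed$damage - params$z) + params$h_b
  H <- c(0, cumsum(haz[-length(haz)]) * dt)
  Ht <- H[match(round(times / dt), round(ed$times / dt))]
  E <- stats::rexp(n)
  vapply(Ht, function(h) mean(E > h), numeric(1))
}

mc_survival_it <- function(params, profile, times, n, dt = 0.01) {
  ed <- euler_damage(profile, params$k_d, max(times), dt)
  runmax <- cummax(ed$damage)
  mx <- runmax[match(round(times / dt), round(ed$times / dt))]
  u <- stats::runif(n)
  thr <- params$alpha * (u / (1 - u))^(1 / params$beta)
  bg <- if (params$h_b > 0) stats::rexp(n, params$h_b) else rep(Inf, n)
  vapply(seq_along(times), function(i) {
    mean(thr > mx[i] & bg > times[i])
  }, numeric(1))
}

# exact multinomial path probability of an observed survivor sequence
multinomial_path_loglik <- function(n0, surv, S) {
  q <- c(1, S)[-(length(S) + 1)] - S        # interval death probabilities
  d <- c(n0, surv)[-(length(surv) + 1)] - surv  # interval deaths
  lgamma(n0 + 1) - sum(lgamma(d + 1)) - lgamma(surv[length(surv)] + 1) +
    sum(ifelse(d > 0, d * log(q), 0)) +
    surv[length(surv)] * log(S[length(S)])
}

# construct a guts_fit-like object with known (fixed) parameters, for
# definitional checks of the performance metrics
make_fixed_fit <- function(params, data, n_draws = 50) {
  model <- if (inherits(params, "guts_params_sd")) "sd" else "it"
  pn <- if (model == "sd") c("k_d", "z", "k_k", "h_b") else
    c("k_d", "alpha", "beta", "h_b")
  est <- unlist(params[c("k_d",
                         if (model == "sd") c("z", "k_k") else
                           c("alpha", "beta"), "h_b")])
  draws <- tibble::as_tibble(as.list(stats::setNames(est, pn)))[
    rep(1, n_draws), ]
  draws <- dplyr::mutate(draws, chain = 1L,
                         iteration = seq_len(n_draws), .before = 1)
  structure(list(
    model = model, draws = draws,
    summary = tibble::tibble(term = pn, estimate = unname(est),
                             conf.low = unname(est),
                             conf.high = unname(est)),
    rhat = stats::setNames(rep(1, 4), pn), converged = TRUE,
    threshold_identifiable = TRUE,
    groups = chirotktd:::build_groups(data), data = data,
    chains = 1L, iter = n_draws, seed = 42L
  ), class = "guts_fit")
}
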