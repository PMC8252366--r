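# chirotktd

Toxicokinetic–toxicodynamic (TK-TD) modelling of acute and chronic
insecticide effects in the midge *Chironomus riparius* — and, more
generally, a tested pipeline for asking *why* chronic lethality can be so
much worse than acute tests predict.

## The scientific problem

Acute water-only tests (48 h, constant or pulsed exposure, immobility
endpoint) and chronic spiked-water sediment tests (28 d, declining
exposure, emergence endpoint) probe the same animal through very different
windows. A survival model calibrated on the acute data can extrapolate to
the chronic time frame — but for some compounds it still under-predicts
chronic mortality by an order of magnitude. This package implements both
layers of the mechanistic explanation:

* **GUTS-RED** (reduced General Unified Threshold model of Survival).
  Scaled damage follows first-order kinetics towards the water
  concentration, `dD/dt = k_d (C_w(t) − D)`. Under **stochastic death
  (SD)** the hazard is `h = k_k · max(0, D − z) + h_b`; under **individual
  tolerance (IT)** each individual draws a fixed threshold from a
  log-logistic distribution (median `α`, shape `β`) and dies when its
  running-max damage exceeds it. Calibration is Bayesian (conditional
  binomial likelihood, adaptive Metropolis MCMC) on censored immobility
  counts; model quality is reported with the EFSA criteria (PPC, NRMSE,
  SPPE), and `lcx()` computes LCx values by bisection for any exposure
  profile.

* **DEB-TK-TD**. A dynamic energy budget model of the larva (structural
  length `L`, scaled reserve density `e`, von Bertalanffy growth towards
  `f·L_m`, pupation triggered at a fixed length `L_p`) is coupled to the
  same scaled damage through *feeding inhibition*: stress
  `s = max(0, (D − z_sub)/c_T)` multiplies the functional response. When
  maintenance cannot be paid the larva shrinks and a starvation hazard
  proportional to the relative shrink rate accrues — starvation is the
  only death mechanism in this layer. Only `z_sub` and `c_T` are estimated
  from chronic data; `k_d` stays fixed at the GUTS-SD value.

If `z_sub` sits far below the GUTS threshold `z`, feeding inhibition
starves larvae at concentrations the acute-calibrated survival model calls
safe — indirect chronic lethality. If `z_sub ≈ z`, both routes agree.

The package ships the published median GUTS-RED parameter sets for
flupyradifurone, imidacloprid and thiacloprid
(`guts_reference_params()`), seeded generators for synthetic acute and
chronic datasets matching the standard test designs, and ggplot2
`autoplot()` methods plus broom-style `tidy()`/`glance()` for all fitted
objects.

## Worked example

Calibrate GUTS-RED-SD on a synthetic acute dataset generated under the
thiacloprid reference parameters, then ask what it implies for a 28-d
chronic test with single-first-order dissipation:

```r
library(chirotktd)

truth <- guts_params("thiacloprid", "sd")
design <- acute_design(
  concentrations = c(0, 10^seq(log10(0.005), log10(0.5), length.out = 7)),
  n_per_group = 50, obs_times = c(4, 8, 24, 48))
acute <- gen_acute(truth, design, seed = 61)

fit <- fit_guts(acute, model = "sd", chains = 3, iter = 2000, seed = 61)
tidy(fit)
#> # A tibble: 4 × 5
#>   term  estimate conf.low conf.high  rhat
#>   <chr>    <dbl>    <dbl>     <dbl> <dbl>
#> 1 k_d    0.0887   0.0746    0.104    1.11
#> 2 z      0.0181   0.0166    0.0193   1.06
#> 3 k_k   36.3     24.7      53.0      1.03
#> 4 h_b    0.00366  0.00245   0.00512  1.01
ppc(fit); nrmse(fit)
#> [1] 100
#> [1] 4.693542
```

The posterior medians sit close to the generating values (`k_d` 0.0881
h⁻¹, `z` 0.0179 mg/L, `k_k` 35.6 L mg⁻¹ h⁻¹, `h_b` 0.00281 h⁻¹): the
posterior predictive intervals cover all observations and the normalised
RMSE is ~5% of the mean observed count.

Now contrast direct and starvation-driven chronic lethality under the
identical declining-exposure scenario (10.7% of the spike remaining after
28 d):

```r
run_mechanism_comparison("thiacloprid", z_ratio = 10)
#> # A tibble: 1 × 6
#>   compound    guts_lc50 deb_lc50 ratio   z_sub      c_T
#>   <chr>           <dbl>    <dbl> <dbl>   <dbl>    <dbl>
#> 1 thiacloprid    0.0213  0.00335  6.35 0.00179 0.000895
```

With a sublethal threshold ten-fold below the GUTS threshold, the DEB
model reaches 50% chronic lethality at 0.0033 mg/L — 6.4× below the 0.021
mg/L chronic LC50 the acute-calibrated survival model predicts. Repeating
with `z_ratio = 1` gives a ratio of 0.64: when the thresholds coincide,
both routes agree within a factor of two. That contrast — indirect
starvation mortality dominating for neonicotinoid-like parameter sets,
negligible when sublethal and lethal thresholds coincide — is the
mechanistic finding the pipeline reproduces.

## Package layout

| file | contents |
|---|---|
| `R/exposure.R` | exposure profiles, SFO dissipation fitting |
| `R/damage.R` | analytic scaled-damage kinetics |
| `R/guts.R` | SD/IT survival, LCx, reference parameter sets |
| `R/calibration.R` | censoring, likelihood, MCMC, EFSA metrics |
| `R/deb.R` | larval DEB model, growth/starvation, emergence |
| `R/tktd.R` | feeding-inhibition coupling, chronic calibration |
| `R/synthetic.R` | seeded acute/chronic/measurement generators |
| `R/pipeline.R` | acute-to-chronic prediction, mechanism comparison |
| `vignettes/methods.Rmd` | models, assumptions, numerical choices |
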