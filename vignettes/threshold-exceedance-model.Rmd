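---
title: "A threshold-exceedance model for teratogenic radiation dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A threshold-exceedance model for teratogenic radiation dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teratodose)
```

## The model

Animal experiments with acute, uniform X-ray exposure suggest a threshold
dose below which teratogenic effects (malformations, stillbirth, perinatal
death after in-utero exposure) do not occur. `teratodose` implements a
tolerance-distribution model that reconciles such shoulder-type
single-dose curves with epidemiological findings of excess perinatal
mortality at population doses three orders of magnitude lower.

Two assumptions drive the model:

* every individual has its own critical (threshold) dose above which DNA
  repair fails — an All-or-None response — and these thresholds are
  lognormally distributed over the population, `X2 ~ LN(mu2, sigma2)`;
* the doses actually received by the population are themselves random,
  also lognormal, `X1 ~ LN(mu1, sigma1)`, rather than one discrete dose.

An adverse outcome occurs when `X1 > X2`. Because `log X1 - log X2` is
normal, the population response probability has the closed form

    P(X1 > X2) = pnorm((mu1 - mu2) / sqrt(sigma1^2 + sigma2^2)).

Plotted against the *mean* dose `exp(mu1 + sigma1^2/2)` of each dose
distribution, the response follows a cumulative lognormal with

    mu    = mu2 + sigma1^2 / 2,
    sigma = sqrt(sigma1^2 + sigma2^2),

a strictly positive, threshold-free curve. The package treats the closed
form as the analytic oracle and verifies it two independent ways: by
quadrature of the threshold density against the dose survival function
(in the test suite) and by Monte Carlo simulation (`simulate_exceedance`,
`run_sweep`).

All logarithms are natural; `mu` parameters are log-medians (log-mSv for
doses, log-Bq/kg for burdens). Units are labels only — the package never
converts between dose and dose rate or between Bq/kg and Gy. The
degenerate `sigma = 0` case (a discrete dose, i.e. a point mass) is
supported everywhere through the cdf, which becomes a unit step at the
median; the density is deliberately an error there.

## Reference study conditions

The default sweep (`sweep_config()`) reproduces the reference simulation:
log-median doses `mu1 = 0, 0.1, ..., 1.0` (11 points), dose spread
`sigma1 = 0.3`, thresholds with median 10 mSv (`mu2 = log 10`) and
`sigma2 = 0.4`, and `N = 1e6` paired draws per point, all driven by one
seed. Each grid point draws a fresh dose sample; event counts are stored
as integers and rates derived from them.

```{r sweep, eval = FALSE}
sw <- run_sweep(sweep_config(seed = 42))
fit <- fit_cumulative_lognormal(sw)
fit_pl <- fit_power_law(sw)
compare_models(fit, fit_pl)
dispersion_ratio_table(sw, fit)
```

With these conditions the fitted location lands near
`log(10) + 0.3^2/2 = 2.348` and the fitted spread near
`sqrt(0.3^2 + 0.4^2) = 0.5`; the power law fits visibly worse (its
deviance is several times the lognormal's at equal df). The
dispersion-ratio table quantifies the central claim: at small mean doses
the response rate with dose dispersion exceeds the discrete-dose
(`sigma1 = 0`) prediction by two orders of magnitude, falling to a
single-digit factor at the top of the grid.

## Fitting scheme and numerical choices

Both curves are fitted by iteratively reweighted nonlinear least squares:

* weights are binomial, `w = N / (p (1 - p))`, recomputed from the
  *fitted* rates after each inner solve, so zero-event points remain
  usable; at rates of 1e-3 and below this is numerically identical to
  Poisson weighting `N/p`;
* the inner weighted solve uses Levenberg-Marquardt
  (`minpack.lm::nlsLM`), which is robust on the flat, banana-shaped
  deviance surfaces these curves produce;
* the outer loop stops when the maximum relative parameter change drops
  below 1e-8 (cap 50 iterations); non-convergence is an error that
  reports the last iterate;
* `sigma` (and the power-law amplitude `a`) are optimised on the log
  scale to enforce positivity and reported on the natural scale with
  delta-method standard errors;
* standard errors come from the weighted Gauss-Newton curvature at the
  optimum, scaled by `sqrt(deviance/df)`;
* starting values: a probit-transform regression of `qnorm(rate)` on
  `log(mean_dose)` for the lognormal curve, ordinary least squares on
  the log-log points for the power law;
* the deviance is the Pearson-type weighted residual sum of squares; at
  the true model it behaves like a chi-squared variable with one degree
  of freedom per point, which the test suite checks by simulation.

`replicate_sigma_study()` repeats the whole sweep-and-fit pipeline
(default 10 replicates on independent seed streams) and summarises the
fitted spreads as z-scores against `sqrt(sigma1^2 + sigma2^2)`, the same
design used to verify the spread relation originally.

## The epidemiological stage

The same excess curve is applied to a monthly perinatal-mortality series
with a lagged exposure term:

    deaths_t ~ Poisson(births_t * rate_t)
    rate_t   = baseline(t) * (1 + A * Lambda(burden(t - lag); mu, sigma))

with `baseline(t) = exp(b0 + b1 t)` (optionally plus an annual sin/cos
pair) and `Lambda` the lognormal cdf on the burden axis, `mu` in
log-Bq/kg. The multiplicative form nests the no-exposure model at
`A = 0`, so the exposure term is tested by an F-test on the deviance drop
(3 numerator df), and the observed/reduced-model rate ratios plotted
against lagged burden are exactly the excess curve `1 + A Lambda`.

No public registry series accompanies the original analysis, so the
package generates synthetic series (`generate_epi_series`). Defaults were
fixed once, to emulate a five-year national registry after a
Chernobyl-scale deposition:

* 60 months of 50,000 births each, baseline 6 perinatal deaths per 1000
  births declining 2 % per year — monthly Poisson noise of a few
  percent, comparable to the error bars of the original rate-ratio
  figure;
* a gamma-shaped burden pulse starting at month 6, peaking at 35 Bq/kg
  at month 18 and decaying over roughly two years (post-Chernobyl
  maternal burdens stayed below ~40 Bq/kg);
* excess-curve truth `mu = 3.97` (median-effect burden ~53 Bq/kg) and
  `sigma = 0.30`, the values reported for the real data;
* amplitude `A = 1.5`, sized before any fitting so the peak excess
  (~12 % of baseline) is unambiguous against the monthly noise: the
  expected deviance drop of the exposure term is ~25, comfortably past
  the "highly significant" anchor; `A` is not stated for the real data;
* exposure lag 7 months (burden of pregnant women affects perinatal
  mortality seven months later).

The fit mirrors the generator with Poisson weights `births/rate`,
refreshed from fitted rates; because the deviance surface has a long flat
ridge (see below), the outer loop also accepts a relative deviance change
below 1e-7 as converged, and a small deterministic grid of starting
values guards against start dependence.

`practical_threshold()` makes the "practical threshold" idea exact: the
model has no true threshold, so the package reports the smallest burden
at which the fitted relative excess reaches a stated fraction `epsilon`
of baseline, `exp(mu + sigma * qnorm(epsilon/A))`, with `epsilon = 0.05`
by default and always echoed next to the result. At the reported real-data
estimates and `A = 1`, the 5 % convention gives ~32 Bq/kg; a figure-level
reading of the original curve ("about 20 Bq/kg") corresponds to a looser
convention near 1-2 %.

## Known limitations

**Weak identifiability of the excess triple.** With burdens confined to
(0, 40] Bq/kg and a median-effect burden of 53 Bq/kg, the data only ever
sample the lower tail of `Lambda`. Different triples `(A, mu, sigma)`
then produce nearly identical excess curves over the observed range, and
the minimum-deviance fit frequently collapses onto a steeper, lower-`mu`
member of that near-equivalence class with a deceptively small curvature
standard error. In repeated synthetic experiments at the default scale,
`mu` is recovered within three reported standard errors in only about
half the replicates, and raising the amplitude to implausible values does
not cure it. Point estimates of `mu` and `sigma` from series of this
size and burden range — including real ones — should therefore be read as
a description of the observable lower tail, not as precise curve
parameters. The F-test of the exposure term is unaffected: under a null
amplitude it rejects at close to its nominal 5 % level, and under the
default effect it is essentially always highly significant.

**What the generator does not emulate.** Real registry series carry
seasonality, slowly varying demographic structure, overdispersion
relative to Poisson, reporting artifacts, and spatial heterogeneity in
exposure; the generator has none of these unless the seasonal pair is
switched on. Passing tests therefore demonstrate correct behaviour of
the estimator under the model's own assumptions, not the validity of the
model for any particular registry.

**Scale of the verification runs.** The test suite runs the full
11-point, 1e6-trial sweeps for the headline checks, 50 replicate sweeps
for the model-preference rate, and 100 effect / 400 null replicates of
the 60-month epidemiological stage; the deviance-distribution and
recovery-of-relations checks use smaller trial counts (1e3-2e5) chosen so
their sampling noise is still far below the tolerances being asserted.

## Interfaces

Sweeps and mortality series travel as plain CSV
(`mu1,mean_dose,events,trials,rate` and `period,births,deaths,burden`),
fits as JSON, and every command-line run writes a metadata record with
the config echo and seed. The `exec/teratodose` script exposes the
pipeline as subcommands (`sweep`, `fit`, `table`, `verify-sigma`,
`epi-simulate`, `epi-fit`, `epi-run`); plots are optional artifacts and
no computation depends on them.
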