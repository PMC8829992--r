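# teratodose

Threshold-exceedance modelling of teratogenic radiation dose–response.

Shoulder-type survival curves from mouse experiments are usually read as
evidence for a threshold dose (~100 mSv) below which in-utero radiation
exposure causes no adverse outcomes, yet epidemiological series show
excess perinatal mortality at population doses around 1 mSv. `teratodose`
implements a tolerance-distribution model that resolves the apparent
contradiction: both the dose received and the individual critical
(threshold) dose are lognormal random variables, and an adverse outcome
occurs when an individual's dose exceeds its own threshold.

For dose `X₁ ~ LN(µ₁, σ₁)` and threshold `X₂ ~ LN(µ₂, σ₂)`,

```
P(response) = P(X₁ > X₂) = Φ( (µ₁ − µ₂) / √(σ₁² + σ₂²) ),
```

so plotted against the mean dose `exp(µ₁ + σ₁²/2)` the dose–response
curve is a cumulative lognormal with location `µ = µ₂ + σ₁²/2` and
spread `σ = √(σ₁² + σ₂²)` — strictly positive at every dose, with no
threshold. Dose *dispersion* (σ₁ > 0) is the key amplifier: at small
mean doses the population response exceeds the discrete-dose prediction
by two orders of magnitude. The package provides:

* closed-form lognormal primitives and exceedance probabilities
  (`exceedance_probability`, `derived_response_curve`);
* a seedable Monte Carlo simulator sweeping the dose log-median over a
  grid (`run_sweep`, default 11 points × 10⁶ paired draws);
* iteratively reweighted nonlinear least-squares fits of
  cumulative-lognormal and power-law curves, with deviances, F-tests and
  dispersion-ratio tables (`fit_cumulative_lognormal`, `fit_power_law`,
  `dispersion_ratio_table`);
* a replicate study verifying `σ = √(σ₁² + σ₂²)`
  (`replicate_sigma_study`);
* a synthetic epidemiological stage: monthly perinatal-mortality series
  with a 7-month-lagged cumulative-lognormal excess driven by a cesium
  body-burden pulse, the matching Poisson-weighted fit, rate-ratio
  curves, and a practical-threshold readout (`generate_epi_series`,
  `fit_epi_model`, `rate_ratio_curve`, `practical_threshold`);
* a command-line interface (`exec/teratodose`, or `run_cli()` from R).

## Worked example

```r
library(teratodose)

sw  <- run_sweep(sweep_config(seed = 42))   # sigma1 = 0.3, N = 1e6/point
fit <- fit_cumulative_lognormal(sw)
fit
#> cumulative_lognormal fit (converged, 3 iterations)
#>              mu  sigma
#> estimate 2.3237 0.4922
#> SE       0.0176 0.0061
#> Deviance: 12.9 on 9 df

compare_models(fit, fit_power_law(sw))
#> cumulative_lognormal: deviance = 12.9; power_law: deviance = 39.9 (df = 9)
#> Preferred: cumulative_lognormal
```

The fitted location sits at the derived value `log(10) + 0.3²/2 = 2.348`
within two standard errors, and the fitted spread at
`√(0.3² + 0.4²) = 0.5`; the power law is clearly worse at equal degrees
of freedom. The dispersion-ratio table compares the fitted curve with
the discrete-dose (`σ₁ = 0`) prediction at the same mean doses:

```r
tail(dispersion_ratio_table(sw, fit), 3)
#>    mu1 mean_dose predicted_with predicted_without  ratio
#> 9  0.8    2.3274         0.0013             1e-04 9.9331
#> 10 0.9    2.5737         0.0026             3e-04 7.3918
#> 11 1.0    2.8436         0.0047             8e-04 5.6303
```

i.e. even at the top of the grid (mean dose 2.84 mSv) dose dispersion
raises the response rate more than five-fold; at the bottom of the grid
the factor is in the hundreds.

The same pipeline runs from the shell:

```sh
exec/teratodose sweep --seed 42 --out runs/demo
exec/teratodose fit --in runs/demo/sweep.csv --model both --out runs/demo
exec/teratodose epi-run --seed 11 --out runs/epi --epsilon 0.05
```

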