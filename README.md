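# ccdlnm

Case-crossover distributed lag non-linear models for hourly environmental
exposures.

`ccdlnm` is for epidemiologists studying whether short-term weather stress —
a cold snap, a spell of dry air — triggers acute events such as
intracerebral hemorrhage (ICH) in the hours before onset. It implements the
complete analysis pipeline:

* **time-stratified case-crossover design**: each patient's onset hour is
  compared with every other same-weekday, same-hour occurrence in the same
  calendar month, so all time-invariant confounders, seasonality and
  circadian structure cancel;
* **distributed lag non-linear model (DLNM)**: the effect of an exposure
  history enters through a cross-basis
  `W[i,(j,k)] = Σ_l B_j(x_{t−l}) C_k(l)`, with natural cubic splines
  (default 3 df) in the exposure dimension and a natural spline with
  log-spaced knots in the lag dimension (0–24 h by default), giving a
  smooth fitted surface `f(x, l) = Σ β_jk B_j(x) C_k(l)`;
* **exact conditional logistic regression**: the one-case-per-stratum
  matched-set likelihood `ℓ(β) = Σ_s [x_case·β − log Σ_j exp(x_j·β)]`,
  maximised by Newton–Raphson with step-halving and separation detection;
* **effect summaries**: lag-specific and cumulative odds ratios contrasting
  an extreme exposure (default the 1st percentile) against a reference
  (default the 99th), with delta-method 95% CIs; exposure–lag–response
  surfaces; subgroup z-tests; a temperature × humidity interaction
  likelihood-ratio test; and a nine-variant sensitivity grid;
* **exposure preparation**: nearest-station assignment with a 50 km cutoff,
  backward 24-h lag matrices, two-stage percentile trimming of extreme
  values, and 24-h mean pollutant covariates;
* **a seeded synthetic-data generator** (hourly subtropical weather with
  annual/diurnal cycles, AR(1) noise and temperature–humidity
  anticorrelation; onset events drawn by thinning from a known
  exposure–lag–response surface) so every stage of the pipeline is
  verifiable against ground truth.

## Worked example

Simulate two years of hourly weather at two stations, draw 2000 onsets from
a known cold-effect surface, and run the full analysis:

```r
library(ccdlnm)

stations <- simulate_weather(weather_config(
  start_time = "2020-01-01 00:00", end_time = "2021-12-31 23:00",
  n_stations = 2, seed = 42))
truth    <- recovery_truth()        # known surface, true OR(0-24 h) = 2.48
patients <- simulate_onsets(stations, truth$truth, n_cases = 2000, seed = 43)

fit <- cc_dlnm(patients, stations, run_config())
fit
#> <cc_dlnm> case-crossover DLNM fit
#>   patients in: 2000; within station radius: 2000; strata fitted: 1901
#>   temp_c: contrast 1.67 vs reference 30.5
#>   rh_pct: contrast 44.5 vs reference 100
#>   cumulative odds ratios:
#>     temp_c lag 0-12: OR 0.82 (95% CI 0.30-2.24)
#>     temp_c lag 0-16: OR 0.82 (95% CI 0.29-2.33)
#>     temp_c lag 0-24: OR 2.04 (95% CI 0.67-6.25)
#>     rh_pct lag 0-6: OR 1.04 (95% CI 0.59-1.83)
#>     rh_pct lag 0-3: OR 0.89 (95% CI 0.52-1.52)
#>     rh_pct lag 0-24: OR 0.73 (95% CI 0.31-1.70)
```

Reading the output: the pipeline trimmed extreme hourly values, dropped 99
strata whose case hour or entire control set lost exposure support, and
contrasts the 1st-percentile temperature (1.67 °C) against the
99th-percentile reference (30.5 °C). The full-window cumulative odds ratio
for cold, OR 2.04 (0.67–6.25), brackets the generator's true value of 2.48;
humidity, which has no true effect in this simulation, stays near 1. Lag-by-
lag estimates are in `fit$effects$lag` (or `tidy(fit)`), and
`autoplot(fit)` / `plot_lag_pattern()` / `plot_surface()` draw the standard
figures.

The interaction test refits with a temperature × humidity block:

```r
res <- cc_dlnm(patients, stations, run_config(interaction = TRUE))
res$interaction_test
#> # A tibble: 1 × 3
#>   statistic    df p.value
#>       <dbl> <int>   <dbl>
#> 1      15.4    15   0.420
```

`run_sensitivity_suite(patients, stations, run_config())` refits the nine
standard sensitivity variants (no pollutants; spline df 4; max lag 36 h and
48 h; extremes retained; contrast percentiles 2.5/5/10/15) and tabulates
the primary cumulative OR per exposure, and
`subgroup_effects(..., by = "sex")` compares subgroup estimates with
z-tests.

See `vignettes/case-crossover-dlnm.Rmd` for the model, its assumptions, all
tunable parameters, and the verification experiments (oracle equivalence,
500-replicate parameter recovery, and null calibration of the tests).

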