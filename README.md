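# extremeair

Extreme-value modeling of unhealthy air pollution events from hourly Air
Pollution Index (API) series.

## The problem

Urban air quality in Malaysia is tracked by the API: each hour, five
pollutant concentrations (CO, O3, NO2, SO2 in ppm; PM10 in µg/m³) are mapped
through piecewise-linear sub-index formulas onto a common scale, and the API
is the maximum of the available sub-indices. An API above 100 marks an
*unhealthy* air pollution event; above 300, *hazardous*. Risk assessment for
such events — "how high an API should we expect once in 10 years?" — is an
extreme-value problem, and the answer depends critically on *which*
observations count as extreme:

- **Block maxima (BM)**: one maximum per calendar year, fitted with a
  generalized extreme-value (GEV) distribution. Unbiased but wasteful — a
  24-year record gives 24 points and large standard errors.
- **Peaks-over-threshold (POT)**: every hourly value above `u = 100`, fitted
  with a generalized Pareto distribution (GPD). Thousands of points and small
  standard errors, but pollution episodes last hours to days, so consecutive
  exceedances are strongly dependent and the fit is biased.
- **Mixed POT-BM**: group the exceedances into maximal runs (POT blocks),
  *decluster* them so retained blocks are separated by at least `r = 240`
  hours, and keep one observation per block — its maximum — fitted with a
  GEV. This keeps many more points than BM while restoring approximate
  independence: a balanced bias–variance tradeoff.

`extremeair` implements all three selection strategies, the GEV/GPD machinery
around them (L-moment and maximum-likelihood estimation with standard
errors, return levels with delta-method confidence intervals), diagnostics
(mean-residual-life curve, ACF with white-noise band, PP points,
model-comparison tables), and a seeded generator of synthetic hourly
API-like series with clustered exceedance episodes for validation.

## Models

GEV (Hosking shape convention; location ξ, scale α, shape κ):

    G(y) = exp{ −[1 − κ(y−ξ)/α]^{1/κ} },   κ ≠ 0
    G(y) = exp{ −exp[−(y−ξ)/α] },          κ = 0

fitted either by L-moments (κ̂ = 7.859c + 2.9554c², c = 2/(3+τ̂₃) − ln2/ln3)
or by numerical maximum likelihood. GPD for excesses y = x − u (Coles
convention; scale σ, shape ξ):

    H(y) = 1 − (1 + ξy/σ)^{−1/ξ},   ξ ≠ 0

fitted by maximum likelihood, with the exceedance rate ζᵤ = k/n and return
level y_m = u + (σ/ξ)[(mζᵤ)^ξ − 1]. The two shape conventions are related by
κ = −ξ.

## Worked example

```r
library(extremeair)

# synthetic 24-year hourly API series: baseline mean ~55, sd ~21, with
# Poisson-arriving multi-day exceedance episodes above 100
series <- simulate_series(episode_model(span_years = 24, seed = 1))

# mixed POT-BM selection: threshold 100, 240 h declustering
potbm <- select_extremes(series, "potbm", u = 100, r = 240)
potbm
#> Extreme sample (POT_BM): k = 44 of n = 210240 observations, threshold = 100, min separation = 240 h

fit <- fit_gev_mle(potbm)
fit
#> GEV fit (MLE, Hosking shape convention), n = 44
#>           location    scale   shape
#> estimate  234.8438 100.5581 -0.2512
#> std_error  17.1352  13.9479  0.1231
#> log-likelihood: -278.643

return_level_curve(fit, c(5, 10, 50))
#>   period    level   ci_low   ci_high
#> 1      5 418.0175 339.5010  496.5341
#> 2     10 539.0524 406.0718  672.0330
#> 3     50 901.2715 493.1419 1309.4010
```

The fitted negative Hosking shape (κ̂ ≈ −0.25, i.e. Coles ξ ≈ +0.25) says
the episode maxima are heavy-tailed, inherited from the generator's GPD
excess shape of 0.29. The 10-year return level of ≈539 index points is the
API level expected to be exceeded by one declustered episode per decade;
intervals widen rapidly with the return period, which is why short-horizon
(5–10 year) estimates are the ones to act on. Raw POT exceedances from the
same series fail the independence diagnostic that POT-BM passes:

```r
acf_diagnostic(pot_exceedances(series, 100)$values, 30)$acf[2]   # lag-1 ACF
#> [1] 0.6312734   # far outside the white-noise band
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
inst/exec/extremeair simulate --years 24 --seed 1 --out series.csv
inst/exec/extremeair select --method potbm --threshold 100 --min-sep-hours 240 \
    --input series.csv --output sample.csv
inst/exec/extremeair run --input series.csv --method potbm --out report/
```

Exit codes: 0 success, 2 validation error, 3 convergence failure,
4 insufficient extremes.
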