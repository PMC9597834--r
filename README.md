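# graywhaleforage

Multi-dimensional analysis of foraging habitat use at a coastal gray whale
feeding site, for movement ecologists and passive-acoustic-monitoring
analysts working with long line-transect, photo-identification and call-log
time series.

A site like this is observed three ways at once: repeated transect surveys
count and locate every foraging whale; photo-ID builds per-individual
sighting histories; a moored recorder logs calls and per-minute ambient
noise. The package turns those tables into the standard multi-dimensional
analysis:

* **Seasonal foraging intensity** — mean/maximum whales per transect, peak
  date (days from 24 May), skewness and excess kurtosis of the season's
  counts, and the high/low classification against the global mean
  whales-per-survey.
* **Time-series diagnostics** — ACF/PACF with 95% bands, persistence
  (naïve) forecast residuals `obs[t] − obs[t−1]` on a chronological 66/34
  split, Dickey-Fuller stationarity, runs test, Ljung-Box, and lagged
  cross-correlation with pairwise deletion.
* **Site fidelity** — inclusive residency spans (single sighting = 1 day),
  return vs single-visit classification (sightings spanning ≥ 2 years),
  per-year return proportions, and Spearman correlations against foraging
  intensity.
* **Spatial use** — whale-count-weighted mean locations, monthly half-open
  heat grids exported as GeoJSON, and per-transect social context: a
  haversine distance matrix over foraging units with nearest-neighbour
  summaries.
* **Acoustic context** — aural-visual sampling schedules (every fifth full
  day plus transect-concurrent hours), call-class distributions under both
  the all-calls and non-motherese denominators, calls/hour/whale rates,
  visual-acoustic joins with rank correlations, and a Monte Carlo
  detection-range model built on the sonar equation
  `RL = SL − 20·log10(r)` with `SL ~ N(156.9, 11.4)` dB re 1 µPa @ 1 m and
  detection when `RL > NL`; the p = 0.5 radius is
  `r* = 10^((SL_mean − NL)/20)`.
* **Driver importance** — a lagged (0-4 yr) whale/environment feature
  table, Spearman screening, and per-variable importance as the normalized
  explained-deviance share of univariate penalized-spline GAM fits.
* **Synthetic data** — a seeded generator coupling a logistic prey stock to
  threshold-attracted Poisson whale counts, loyal/single-visit sighting
  histories with an injected 10-day residency gap, northward within-season
  location drift, and call streams whose knock/moan mixture crosses over
  with inter-individual distance. The generator's truth is retained so
  every estimator is tested by parameter recovery.

## Worked example

```r
library(graywhaleforage)

cfg <- simulation_config(seed = 42L)   # 20 seasons, surveys every 2-3 days
ds  <- simulate_foraging_data(cfg)
ds
#> <gw_dataset>
#>   749 transects over 20 seasons; 3294 whale observation units
#>   catalogue: 179 individuals, 8550 sightings
#>   acoustics: 993 calls, 4320 noise minutes

ann <- summarize_seasons(ds$transects)
ann[1:3, c("year", "mean_whales", "max_whales", "peak_date_days", "classification")]
#>    year mean_whales max_whales peak_date_days classification
#> 1  1997        6.43         13             44           high
#> 2  1998        6.40         14             10           high
#> 3  1999        5.36         13             39           low
round(ann$global_mean[1], 2)
#> [1] 6.21

classify_catalogue(ds$catalogue)
#> <gw_fidelity>
#>   179 individuals: 87 return (48.6%), 92 single-visit (51.40%)
#>   20 catalogue years

diagnose_series(ds$transects$n_whales[order(ds$transects$date)])
#> <gw_diagnostics>
#>   Dickey-Fuller: statistic -23.3472 (p ~ 0.010); runs test p = 0.034
#>   persistence residuals: n 255, mean -0.0078, sd 3.817, range [-11.0, 13.0]

detection_radius_series(ds$noise, detection_model())
#> <gw_radius_series> 4320 minutes; radius exceeded 10% of the time: 6532 m,
#>   median 1990 m, exceeded 90%: 581 m
```

Reading the output: the site sustains ~6.2 whales per survey overall, with
seasons classified high or low against that threshold; the strongly
negative Dickey-Fuller statistic says the concatenated count series has no
unit root (no trend/seasonality in survey timing); about half the
catalogued whales are multi-year return whales; and under the ambient-noise
conditions the median call-detection radius is ~2 km, covering the bay,
with a ~0.6 km floor in the noisiest minutes.

`run_pipeline(cfg, "out/")` executes every stage and writes
`transects.csv`, `annual_summary.csv`, `diagnostics.json`,
`fidelity_summary.csv`, `weighted_means.csv`, monthly `heatgrid_*.geojson`,
`call_summary.csv`, `detection_radii.csv`, `joined_context.csv`,
`importance.json` and a seed-stamped manifest; reruns with the same
configuration are byte-identical.

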