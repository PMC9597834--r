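---
title: "Models and methods for multi-dimensional foraging-habitat analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-dimensional foraging-habitat analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graywhaleforage)
```

## The analysis problem

A coastal gray whale foraging site is observed for two decades with three
instruments: repeated line-transect surveys counting and locating every
foraging whale, photo-identification building per-individual sighting
histories, and (in the final seasons) a moored passive acoustic recorder.
The questions the package addresses are the standard ones of quantitative
movement ecology at such a site: how intense is foraging each season and
does a heavy season depress the next (top-down predator-prey lag); which
whales come back and for how long (site fidelity); where in the site does
foraging concentrate through the summer (spatial use); does calling
behaviour track the social configuration of foraging whales
(acoustic context); and which lagged whale-derived or environmental
variables best explain year-to-year variation (drivers).

Because field data of this kind are rarely distributable, the package
includes a synthetic-data generator whose output carries the statistical
structure each analysis stage assumes. Every stage is therefore testable
end-to-end: the generator injects a known truth and the analysis must
recover it.

## Seasonal summaries and the high/low classification

A season is described by its mean and maximum whales per transect, the
peak date (days elapsed from the 24 May season opening; ties broken to the
earliest date, consistent with the typical early-to-mid-summer pressure of
a right-skewed season), and the adjusted Fisher-Pearson sample skewness
and excess kurtosis of the count series. The estimator choice matters only
for small seasons and these are the most widely reported defaults; both
excess and raw kurtosis are emitted because conventions differ. Seasons
with fewer than three transects or fewer than two distinct counts get `NA`
shape statistics rather than a zero division.

Zero-whale transects stay in the denominator of the mean, since
whales-per-survey is defined over all completed surveys. The high/low
classification compares each season's mean to the global mean over all
transects of all years, read strictly: a season exactly at the global mean
is "low". `classify_years()` is idempotent; reclassifying a classified
table reuses its recorded threshold.

## Time-series diagnostics

The within-season and between-year count series are summarised by:

* **ACF/PACF** with the biased (1/n) estimator and white-noise bands at
  `±1.96/√n`. Unit tests pin both against independent brute-force oracles
  (the direct covariance formula; Yule-Walker solves) on all short series.
* **Persistence-forecast residuals** `obs[t] − obs[t−1]` evaluated
  chronologically on the final 34% of the series (the model itself has no
  parameters, so the 66% "training" share only fixes the evaluation
  window). Reported as count/mean/sd/min/max.
* **Dickey-Fuller test**, non-augmented by default (augmentation order is
  configurable) with an intercept. No unit-root package is declared as a
  dependency, so the regression is built on `lm()` with MacKinnon
  response-surface critical values and a p-value interpolated from
  tabulated quantiles of the tau distribution; the p-value is consequently
  approximate (clamped to [0.001, 0.999]) while the statistic and critical
  values are exact. Tests verify size (~5% under a random walk) and power
  (i.i.d. noise rejected) by simulation.
* **Runs test** about the median, dropping median ties, with the two-sided
  normal approximation.
* **Ljung-Box** statistics per included lag (monotone nondecreasing), and
  **lagged cross-correlation** with pairwise deletion of missing years —
  no interpolation is attempted, and any lag with fewer than three
  overlapping years is flagged undefined.

The within-season analysis concatenates all transects across years in date
order, deliberately treating the winter gap as contiguous so that
end-of-season whale numbers can inform the next spring; a per-year mode is
available through `diagnose_series()` on any subset. Lags are in transect
index units throughout.

## Site fidelity

Residency is the inclusive span between first and last sighting of a
season (`last − first + 1`), so a single sighting yields one day — an
exclusive span would make the observed one-day minimum impossible. A whale
is a *return* whale when its sightings span at least two distinct years,
assessed retrospectively over the whole catalogue; the per-year table also
carries a prospective `resighted_proportion` (already known from an
earlier season) which exhibits the catalogue-establishment bias of early
years — it starts at zero by construction. Both the retrospective and
prospective views are emitted because per-year fidelity tables in the
field mix them. Yearly mean residency is provided with and without
single-sighting whales, as published residency averages rarely state which
convention they use. Associations between fidelity and
foraging-intensity metrics use two-sided Spearman rank correlations.

## Spatial use

"Straight-line" inter-individual distances are computed as great-circle
(haversine) distances in metres: at the 0.1-10 km scale of a bay they
agree with planar distances to well under 0.1% and avoid an arbitrary
projection choice. Groups share one location and enter the distance
matrix as one unit; cow-calf pairs likewise (and contribute one whale to
counts). A transect with a single unit has no inter-individual distance —
the mean nearest-neighbour distance is `NA`, never zero. Heat grids use
half-open cells anchored at the bounding-box corner (boundary points go to
the higher cell; an epsilon guards floating-point shortfall), conserve
whale counts exactly, and are exported as GeoJSON polygons. Cell size is
a free parameter with no claimed default: published maps rarely state
their raster resolution, so it is left to the analyst (the pipeline uses
0.01 degrees, roughly 1 km, matching the scale of the bays involved).

## Acoustic context and the detection model

The aural-visual subsampling schedule takes one full 24-h day every fifth
day from the first full deployment day (~20% day coverage) plus
transect-concurrent hours; overlap between the two is reported as-is
rather than deduplicated, since the sampling fractions are descriptive.
Call-class shares are always reported against both denominators (all
calls, and non-motherese calls): published shares mix the two, and the
motherese category — recorded only between mothers and calves — is
excluded from all per-whale foraging call rates.

Detection is modelled by the sonar equation `RL = SL − TL(r)` with
spherical spreading `TL = 20·log10(r/1 m)` and the rule `RL > NL`
(strictly greater; no detection-threshold offset is added, though one can
be folded into `NL`). Source level is normal with mean 156.9 and sd
11.4 dB re 1 µPa @ 1 m, the published moan source level. The Monte Carlo
estimator (default 1e5 draws, explicit seed) is the primary path; the
closed form `Φ((SL_mean − 20log10(r) − NL)/SL_sd)` serves as the
independent oracle in tests, with agreement required within 3 Monte Carlo
standard errors on a grid of ranges and noise levels. The per-minute
"detection radius" is defined at detection probability 0.5 (no published
probability criterion exists, and 0.5 makes the closed form
`10^((SL_mean − NL)/20)` parameter-free); the distribution of per-minute
radii is summarised by the radii exceeded 10% and 90% of the time.
Attenuation beyond geometric spreading is neglected, appropriate for
low-frequency calls over bay-scale ranges.

## Driver importance

The feature table holds one row per year and every variable at lags 0 to
4 — four years being the depth at which a heavy season can still echo in
the counts. Whale-derived metrics (mean, maximum, peak date, skew,
kurtosis, return proportion) enter the importance ranking with a lag of at
least one year: a season's whale numbers regressed on its own
contemporaneous metrics is circular. Environmental variables remain
available at lag 0. Predictors are first screened by pairwise Spearman
correlation (cap 0.95; the later column of a near-duplicate pair is
dropped), then each surviving predictor is fitted alone in a univariate
penalized-spline GAM (`mgcv`, basis dimension 5, GCV smoothing — small
because only ~20 annual rows exist) and importance is that fit's explained
deviance, normalized to shares summing to one. Univariate fits read each
variable's influence without the influence of the others; a multi-term
fit on 16-20 complete rows would be badly overparameterised. The shares
are a declared importance convention, deterministic given the data, and
are not comparable numerically across differently specified importance
procedures.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions everything downstream is validated under:

* **Seasons and surveys.** 20 seasons, 24 May - 6 September, 30-45
  completed transects per season (surveys every 2-3 days), uniformly
  placed survey days.
* **Prey-whale dynamics.** A latent prey biomass (capacity 500 a.u.)
  recovers logistically between seasons at rate 0.5/yr — calibrated so a
  halved stock takes 3-4 winters to rebuild, the lag the between-year
  autocorrelation analysis looks for. Within a season each whale-day
  removes 0.08 units. Transect counts are Poisson with intensity 0.12 per
  unit of prey excess over an attraction threshold of 130, where the
  operative excess is the average of the season-arrival excess and the
  current excess: whales choose the site on arrival and only partially
  leave as it depletes. This blend makes counts decline through a heavy
  season (right-skewed pressure, early peaks) and lets consumption
  overshoot the threshold, so one season's Poisson noise feeds back
  negatively into the next season's prey — the high/low alternation of
  the annual means. Five unrecorded burn-in seasons precede year one so
  the series starts at the stochastic steady state; at these defaults the
  stationary global mean is ~6-7 whales/survey, the scale of a moderately
  used coastal site. With removal strong enough to halve standing prey in
  a high year *and* recovery fast enough to rebound in one winter, annual
  means alternate and their lag-1 autocorrelation is negative in most
  replicates; with the default 3-4-year recovery the dependence spreads
  to longer lags instead.
* **Catalogue.** A loyal pool of 60 whales returns independently each year
  with probability 0.65 and holds residencies of mean 28 days; single-visit
  whales arrive as a Poisson draw proportional to mean excess prey
  (0.06 whales per unit) with mean residency 18 days — the injected 10-day
  residency gap that the recovery tests re-estimate. Residency also shifts
  with standardized prey excess (+6 days per sd), coupling fidelity
  metrics to foraging intensity. Whales are photo-captured on 80% of the
  survey days inside their residency window, emulating dedicated
  photo-ID effort; at this density the span estimator recovers the
  injected gap to within about one day (window-edge effects attenuate it
  slightly — the recovered mean sits near 9.1 days).
* **Locations.** Units scatter (sd 0.012 deg) around a bay centre that
  drifts north by 0.012 deg latitude per month — the south-to-north
  within-season movement; cow-calf pairs are displaced away from the
  corpus by an offset growing with the number of whales present.
* **Calls and noise.** Per-whale Poisson call counts per hour; knock and
  moan intensities cross over logistically at a 500 m mean
  nearest-neighbour distance (scale 200 m), sweeps are
  distance-independent, rumbles rare, and motherese is emitted only when
  cow-calf pairs are present. Ambient noise is i.i.d. normal
  (91 ± 8 dB re 1 µPa per minute), chosen once so the implied p=0.5
  detection radii have a ~2 km median with ~0.6 km noisy-tail and ~6 km
  quiet-tail exceedance radii — the magnitudes a mid-bay coastal
  deployment reports.

What the generator does *not* emulate: weather-driven survey gaps and
aborted transects, observation error in counts and positions, coastline
geometry (locations are unconstrained Gaussian scatter), non-stationary
catalogue effort (every season has photo-ID coverage), within-season
arrival/departure waves beyond the depletion response, and any
correlation structure in ambient noise (tides, storms, vessels). Passing
tests therefore demonstrate that the estimators recover known structure
of the assumed kinds; they do not validate the estimators against the
messier failure modes of real survey data.

## Numerical and design choices

* One RNG substream per sub-generator (dynamics, catalogue, locations,
  noise, calls), derived deterministically from the master seed, so any
  module can be regenerated independently and an identical configuration
  is bit-identical.
* Peak-date ties to the earliest date; classification boundary to "low";
  residency inclusive; heat-grid cells half-open — each tie-break is
  stated in its function's documentation and pinned by a test.
* Degenerate inputs are flagged, not silently zeroed: constant series
  (ACF undefined), single-unit snapshots (no NN distance), sub-3-year
  overlaps (cross-correlation undefined), noise beyond `SL_mean + 4·SL_sd`
  (radius floored at the 1 m reference).
* Problem sizes in the test-suite property checks are chosen to make each
  property's expected signal several times its Monte Carlo noise at
  desk-scale run times: 100 replicates for recovery rates, 200 for the
  lag-1 sign check, 500 for test calibration, 1e5 draws for the detection
  model.

## Known limitations

The Dickey-Fuller p-value is interpolated, not exact; use the critical
values for decisions at conventional levels. The importance shares
depend on the declared univariate-GAM convention and should not be
compared against differently defined importance outputs. The generator's
prey model is a deliberately minimal stand-in — a logistic stock with
threshold attraction — and its within-season arrival process is a
modelling choice, not an inference about the real mechanism. Detection
modelling stops at spherical spreading; sites with strong multipath or
attenuation need a propagation model outside this package's scope.
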