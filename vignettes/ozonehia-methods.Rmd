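---
title: "Methods: projecting ozone-attributable mortality under climate and population change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting ozone-attributable mortality under climate and population change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozonehia)
```

`ozonehia` chains five models: a synthetic-data generator with known ground
truth, exposure-metric construction, bias-correction spatial disaggregation
(BCSD) of coarse chemistry–climate-model ozone, attributable-fraction
health impact assessment, and Monte Carlo uncertainty with a four-factor
driver decomposition. This vignette documents the assumptions, the
parameters that matter, the numerical choices, and what passing tests do
and do not establish.

## The exposure metric

The daily exposure is MDA8, the maximum of the 17 running 8-hour means that
start at local hours 0–16 (no cross-midnight windows — the standard
regulatory convention). A window counts if at least 6 of its 8 hours are
valid; a day counts if at least 75% of its 24 hourly slots (18 hours) are
valid. Missing days are excluded from all downstream means and sums, never
imputed. The 75% day rule is part of the metric's definition; the 6/8
window rule and the window layout are our convention, configurable only in
the sense that the code makes them explicit in one function
(`mda8_from_hourly()`).

Mass concentrations convert at a fixed 2.0 µg/m³ per ppb (ozone at the
usual 25 °C / 1013 hPa reporting conditions), so the WHO guideline of
100 µg/m³ is 50 ppb and the concentration–response functions' 10-µg/m³
increment is 5 ppb. Keeping the factor fixed (rather than
temperature-dependent) keeps every printed equivalence exact.

## The synthetic world

Nothing in the pipeline depends on proprietary monitor or climate-model
archives; the generator (`truth_config()`, `generate_*()`) emulates them
with controlled ground truth:

* **Latent truth.** A separable smooth field: overall level 42 ppb, a
  ±10 ppb seasonal cycle peaking mid-July, smooth meridional (±4 ppb) and
  zonal (±5 ppb) gradients, plus a single AR(1) "synoptic" daily anomaly
  (φ = 0.7, σ = 6 ppb) shared by all locations. The AR(1) noise is what
  gives the cell-month distributions enough quantile structure for the
  bias-mapping stage to be non-trivial. The future period reuses the
  historical anomaly stream by day position, so injected trends are exactly
  the configured deltas.
* **Monitors.** One site inside each city, the rest uniform over the
  domain; site-level daily noise σ = 1.5 ppb; a diurnal profile whose
  maximum 8-hour mean is normalized to 1, so a day's MDA8 is the day's
  level up to noise. Whole site-days are dropped at rate 0.106 (the
  reference network's missingness) and individual hours at rate 0.02, so
  both the day-completeness rule and full-day gaps are exercised.
* **Coarse model fields.** The coarse-aggregated truth plus an injected
  additive bias (default constant +17 ppb, the documented mean
  overestimate; optionally a function of quantile and month) plus
  member-specific N(0, 2 ppb) noise — ensemble members share the truth and
  differ only in their noise stream, mirroring perturbed initial
  conditions. Future fields additionally carry per-scenario seasonal
  deltas: warm −4.2 / cold +15.1 ppb (high scenario), warm −16.6 / cold
  −1.7 ppb (moderate scenario).
* **Demography.** Six population scenarios: NOCHANGE (2050 = 2010, rate
  ratios 1) and five SSP-like scenarios with total-size changes of −0.5%
  to −5.6% and strong aging (65–74 share 5.2% → 11.7–14.0%; ≥75 share
  3.0% → 12.0–19.0%). Age structure is national — uniform across cities —
  mirroring the use of national age-structure scenarios on city
  populations. Mortality-rate change ratios for 2050 vs 2010 are 0.68
  (95% PI 0.35–1.02), 0.50 (0.26–0.73) and 0.83 (0.61–1.05) for ages
  5–64, 65–74 and ≥75.
* **Baseline mortality.** City all-cause levels are lognormal with median
  18 deaths/day (mean ≈ 23, right-skewed as in city-level summaries);
  stratum shares are national constants with the age partition summing to
  the all-cause count, an ≥75 : 5–64 ratio of 2.6, and warm/cold season
  means averaging to the annual mean. Real networks have spatially varying
  cause mixes and age structures; the generator deliberately does not.

What the generator does **not** emulate: atmospheric chemistry (no
NOx-titration mechanism behind the cold-season rise — the trend is simply
injected), spatially varying demographic change, monitor siting bias
toward urban cores, instrument drift, or under-5 mortality. Passing tests
therefore demonstrate that the *statistical machinery* is correct —
bias removal, trend preservation, aggregation, attribution arithmetic,
interval construction — not that any particular real-world burden number
is right.

The default domain is a 3 × 3 block of 2.0° × 2.5° coarse cells (each
containing 8 × 10 fine cells of 0.25°), 10 cities and 40 sites, with the
918-day periods 2013-04-27..2015-10-31 and 2053-04-27..2055-10-31. These
sizes are the package's reference study conditions; the test suite
additionally uses a 2 × 2, one-year, 4-city "tiny" world for unit tests.

## BCSD downscaling

**Bias maps.** For each coarse cell and calendar month, all daily values
across the years are pooled (month-matched, not day-matched, to avoid
penalizing the free-running climate model for weather phasing). Empirical
quantiles of the model and observation pools are taken at K = 99 equally
spaced points q = k/(K+1) using the type-7 (linear interpolation)
estimator; the bias is their difference. K = 99 is the common BCSD
practice; it is configurable, and pools smaller than K/2 trigger a
warning rather than an error. A cell-month with no observations is marked
unusable and its cells are excluded downstream (no gap-filling at the bias
stage — filling happens only at the climatology stage, where it is
recorded).

**Correction.** A daily value x is placed on the *historical* model CDF of
its cell-month — its probability position q\* is read off the fitted model
quantiles by linear interpolation, held constant beyond the outer points —
and the bias at q\* is subtracted. Using the historical CDF for future
values encodes the persistence assumption (historical monthly biases carry
into the future); an additive correction follows the anomaly ("subtract /
add") construction throughout. Correction is exactly monotone: between
quantile knots the corrected value has slope ΔQ_obs/ΔQ_model ≥ 0. A
degenerate cell-month (zero model variance) maps everything through
q\* = 0.5. Output is clamped at 0 ppb, as are all later concentration
fields — concentrations are physical.

**Disaggregation.** The temporal scaling factor (anomaly) is the corrected
coarse value minus the coarse observed monthly climatology; it is
bilinearly interpolated from coarse cell centers to fine cell centers with
constant extrapolation beyond the outermost centers, and the fine observed
climatology is added back. Missing coarse anomalies poison only fine cells
that actually weight them. Climatologies are nearest-neighbour-filled per
month with the fill recorded in a `filled` column.

City exposures are weighted means over the fine cells intersecting the
city boundary, with area-fraction weights (the minimal reading of
"weighted mean"; weights are an explicit input table, so
population-weighting can be substituted). Weights are renormalized over
the non-missing cells of each day. Historical city series use the gridded
observations; a station-average mode (`city_series_from_sites()`) is
available for comparison.

## Health impact assessment

With β = ln(1 + pct/100)/5 per ppb (log-linear, the GLM log-link
convention of the source time-series models; the difference from the
linear-proportion reading is < 0.01% at these magnitudes), the
attributable fraction is AF = 1 − e^(−βC) with no threshold, and
attributable daily deaths are the stratum's mean daily deaths times AF.
Annualization divides the covered-day sum by covered days/365.25, so
"annual" totals are comparable across periods with identical coverage
(the 918-day windows are ≈ 2.514 years). Season-specific coefficients
contribute only on their season's days; out-of-season days count as zeros
in the annual coverage, so warm + cold totals are a partition of the year.

Daily C is the same-day city MDA8 by default. The source risk estimates
are defined on a lag-0–3 window; `assess_annual(exposure_window = 4)`
honors that with a right-aligned 4-day moving average. The default stays
at the same-day value because annual sums are nearly invariant to the
window (the tests bound the difference below 0.5% on smooth series).

Future baselines: age strata scale by the age-group population ratio
(size × structure), times the rate-change ratio where the scenario carries
one; cause and season strata keep constant daily counts, since no
projections of cause- or season-specific rates exist. All-age and
age-summed totals are reported separately and legitimately differ (the
age-specific coefficients are not a weighted average of the all-age one).

## Uncertainty and decomposition

Coefficient draws are normal on the reported percent scale with
sd = (CI width)/(2 × 1.959964) — the normality assumption attaches to the
reported interval, and draws are transformed to β afterwards. One draw per
stratum per iteration is shared across cities, so city totals within a
draw are coherent. Negative coefficient draws are retained (the
respiratory CI crosses zero; truncating would bias the interval); negative
*rate-ratio* draws are truncated at zero (rates are physical) with the
truncation count logged. Empirical confidence intervals are the
2.5th/97.5th percentiles (type 7, linear interpolation — the most common
default, recorded in the run manifest) of the pool of draws × ensemble
members (3,000 values at the default 1,000 × 3); pooling rather than
averaging members within draw is the default, and the draw table makes the
alternative a one-line `group_by`. Population-projection uncertainty is
deliberately excluded — the scenarios are the sensitivity analysis.

The decomposition runs the age-stratified assessment under four nested
configurations (no population change; size only; size + aging; size +
aging + rate change) and reports first differences, so the four
contributions telescope to the total exactly, at machine precision; the
no-change scenario has zero size/aging/rate effects by construction.
Central estimates use point coefficients; percent contributions are
relative to the historical age-stratified burden.

## Numerical choices and degenerate inputs

* Quantile and percentile computations are type 7 throughout (one
  convention everywhere, so the fixed-point property — correcting the
  historical model by its own maps reproduces the observed quantiles at
  all K points — holds to interpolation error).
* Bilinear interpolation clamps query coordinates into the coarse-center
  bounding box, giving constant edge extrapolation; an NA corner
  propagates only through strictly positive weights.
* Concentration clamps at 0 ppb after generation, correction, and
  disaggregation.
* `annualize()` errors on zero covered days; `empirical_ci()` requires at
  least two values; reversed date ranges, negative concentrations, unknown
  scenario labels, and out-of-extent sites raise immediate errors.
* Every generator derives an independent stream from the master seed via a
  label hash, so adding a stage never reshuffles another stage's draws,
  and the whole experiment is bit-reproducible from one integer
  (`run_experiment()` writes a manifest with file checksums to prove it).

## Problem sizes used by the tests

The acceptance-level suite runs the study-condition experiment (918-day
periods, 3 × 3 coarse domain, 10 cities, 2 climate scenarios × 6
population scenarios × 3 members, 50 draws), the perfect-model and
injected-bias BCSD checks on the full-period domain, a 1,000-replicate
empirical-CI coverage study (500 draws per replicate), and end-to-end
determinism on a reduced world. These sizes were chosen so the full suite
documents the method's behaviour at the reference design dimensions while
each individual property remains cheap to re-verify.

## Known limitations

* The latent truth is smooth and spatially coherent; downscaling error on
  sharp urban gradients is only probed qualitatively (the resolution
  sensitivity mode), not calibrated against real heterogeneity.
* One chemistry–climate "model", one bias realization: the multi-model
  spread that dominates real projection uncertainty is out of scope, as is
  separating climate from precursor-emission effects within a scenario.
* Quantile bias maps assume the historical bias structure persists; a
  model whose bias drifts with the climate state violates this by
  construction, and nothing in the data can detect it.
* CRFs are inputs, not estimated here; co-pollutant confounding,
  temperature–ozone interaction, long-term (cohort) effects, and under-5
  mortality are excluded.
* Area-fraction city weights ignore within-city population distribution;
  supplying population-based weights changes exposures where population
  and area disagree.
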