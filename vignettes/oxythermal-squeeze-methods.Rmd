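---
title: "Methods: quantifying a reservoir temperature–oxygen squeeze"
author: "habsqueeze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a reservoir temperature–oxygen squeeze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a eutrophic reservoir that stratifies in summer, a cool-water fish
faces two walls at once: surface water warms past its thermal limit while
the hypolimnion is drawn down below its dissolved-oxygen (DO) floor. The
habitable volume is squeezed into a mid-depth band and can reach zero.
`habsqueeze` quantifies that squeeze from three inputs a monitoring
program can realistically supply — an elevation raster of the basin,
daily water-surface levels, and daily 0–10 m temperature/DO profiles at
1 m steps — and then asks two statistical questions: how does daily
suitable volume vary within and across years, and do annual survey
metrics of the fish population co-vary with the prior summer's squeeze?

## Habitat volume model

**Hypsometry.** The area-at-elevation function is the discrete
cell-counting one: `A(z) = #{cells with elevation ≤ z} × cell_area`. It
is stored as an exact right-continuous step function (sorted unique
elevations with cumulative counts) and evaluated with an inclusive `≤`
comparison — a cell exactly at the water plane is submerged. No sub-cell
interpolation is used anywhere, so every area is an integer multiple of
the cell area and the tests can demand *exact* equality against a
per-cell brute-force oracle.

**Combining bathymetry with a DEM.** Surveyed bathymetry often stops at
the conservation pool, while levels can rise into the flood pool.
`combine_bathymetry_dem()` composes the two aligned rasters — bathymetric
elevation where valid, DEM elsewhere — to produce one continuous surface
covering all reachable levels. Composition (rather than any arithmetic
difference of the two rasters) is the only interpretation that yields an
elevation surface; it is this package's stated rule.

**Suitability integration.** For a day with level `L`, depth plane
`d ∈ {0,…,10}` contributes `A(L − d) × 1 m` when its temperature and DO
pass the trait thresholds, else 0. Choices worth making explicit:

* Thresholds are inclusive on both sides (`T ≤ T_max`, `DO ≥ DO_min`):
  a DO *minimum* of 3 mg L⁻¹ is naturally inclusive, and temperature
  inclusivity is adopted for symmetry.
* Eleven one-metre planes (depths 0–10 inclusive) are evaluated, the
  literal reading of "0–10 m at 1 m intervals". `volume_series(depths =
  0:9)` gives the ten-plane variant for sensitivity analysis.
* The plane area is evaluated at exactly `L − d`; levels are used with
  fractional metres, never rounded.
* An NA temperature or DO makes that plane unsuitable under any scenario
  that consults it (never an exception); such planes are counted in the
  `n_missing_planes` attribute so gap-adjacent partial profiles degrade
  gracefully and visibly.
* Four stressor scenarios — none, DO-only, temperature-only, both —
  re-evaluate the same integral with a subset of the thresholds. They
  obey a lattice (`V_both ≤ V_temp_only, V_do_only ≤ V_none`) that the
  tests assert on every simulated date.

## Seasonal reduction and disturbance indicators

The climatology groups by a 366-day canonical calendar (a month-day maps
to the same index every year; Feb 29 is its own day with fewer
contributing years), reporting mean, sample sd (0 when one year), and n.

Annual indicators per trait range, under the both-stressor scenario:

* **Pulse**: the yearly minimum daily volume — the single worst day.
* **Press**: the minimum 14- and 30-day rolling-mean volumes. Windows
  look forward from each calendar day, must lie wholly within the year,
  and are discarded if any member day is unobserved (no partial-window
  averaging, no cross-year windows). The 30-day cap reflects reported
  tolerance of above-preference temperatures for up to about a month.

Years observing fewer than half the June–October days are flagged
`low_coverage` and excluded from the regression screen: if the squeeze
season itself was not observed, its indicators are not comparable. This
conservative rule is this package's choice for gap handling.

A numerical note: rolling means are computed with `zoo::rollapply` but
deliberately *not* through its cumulative-sum fast path, whose roundoff
can turn a window of exact zeros into a value of order −1e−9 — enough to
break the invariants `min_daily ≤ min_avg` and `volume ≥ 0` that the
package guarantees.

Lag-1 autocorrelation of the daily series is the Pearson correlation
over pairs of *consecutive observed dates only*; pairs spanning a gap
are excluded so outages cannot fabricate persistence.

## Trend GAM

Per trait range the package fits

`Habitatₜ = β₀ + f(Habitatₜ₋₁) + f(DayOfYearₜ) + f(Dateₜ) + f(WaterLevelₜ) + εₜ`

with Gaussian errors and identity link via `mgcv::bam` (fast REML,
discretized covariates; `mgcv::gam`/REML as an automatic fallback for
designs too small to discretize). The lagged-response smooth absorbs the
series' strong day-to-day persistence; day of year uses a cyclic cubic
regression spline with knots at days 1 and 366, making the seasonal
effect exactly continuous across the year boundary (verified to ~1e−16
in tests); date (fractional years, `year + doy/365.25`) and water level
use thin-plate splines. Basis dimensions default to k = 10 for lag,
date, and level and k = 20 for day of year — conservative for daily
series whose seasonal feature is a single broad summer trough — and are
capped automatically below the number of distinct covariate values.

Degenerate inputs are reported, not thrown: a constant response yields a
fit object with all edf 0 and undefined R²; a constant predictor drops
that smooth with a warning and reports edf 0. Partial effects are
evaluated on 200-point grids per predictor from `predict(type =
"terms")`, which centres each smooth over the observed data.

`long_term_trend_test()` classifies the date smooth as effectively
linear when edf ≤ 1.1. One honest caveat: under REML smoothness
selection a *truly* linear effect receives edf just above 1 in roughly a
quarter of replicates, so this classification is a majority property
across replicates, not a certainty; the test suite asserts it as such.
Because the lagged response does not necessarily remove all residual
autocorrelation, the fit reports a residual lag-1 ACF diagnostic rather
than asserting independence.

## Regression screen

Survey descriptors (four catch-per-net-night size classes; two
relative-weight classes) from winter gillnetting of year *Y* are paired
with indicators from calendar year *Y − 1* — the previous summer —
with the lag configurable. Each (range × indicator × descriptor) cell
gets an OLS fit with intercept and a two-sided t-test on the slope;
with 3 ranges, 3 indicators, and 6 descriptors this is the 54-model
family, and significance is judged at the Bonferroni-corrected α/54
(0.05/54 ≈ 0.00093; the unrounded value is used internally). A
zero-variance predictor — which genuinely occurs when the strictest
range's yearly minimum is 0 every single year — produces a flagged
degenerate result with NA p-value rather than an error. Missing survey
years are allowed per descriptor (real monitoring series are ragged); no
outlier handling or robust regression is applied, matching the plain-OLS
design this screen mirrors.

## The synthetic lake

The generator produces inputs with the statistical structure the
analysis assumes, from a single master seed (split per component, RNG
state restored afterwards, so reruns are bit-identical):

* **Bathymetry**: an elliptic-paraboloid bowl rescaled to hit the floor
  and rim elevations exactly, with optional clamped Gaussian roughness.
* **Levels**: seasonal sinusoid + AR(1) residual. Defaults (mean 188 m
  AMSL, amplitude 2 m, φ = 0.98, innovation sd 0.15 m) give
  multi-year excursions of roughly 184–192 m — persistent wet and dry
  spells rather than white noise.
* **Profiles**: surface temperature is an annual sinusoid (mean 18 °C,
  amplitude 12 °C, peak day 210). A stratification index s(t) rises as a
  half-sine over the stratified window (days 150–280). Temperature drops
  by `6 °C × s(t) × logistic((d − 6)/1.2)` with depth; DO falls from
  8 mg L⁻¹ toward a 1 mg L⁻¹ hypolimnetic floor with the same logistic.
  These defaults were chosen once so that at peak stratification the
  25 °C isotherm lies *below* the 3 mg L⁻¹ oxycline: the preference
  range closes completely (volume exactly 0), the tolerance range keeps
  a thin mid-depth band, and the acute range loses only its deepest
  planes — the qualitative squeeze pattern of a stratified south-central
  US reservoir. Winter columns are exactly uniform, so all ranges
  recover to the unconstrained volume.
* **Survey**: `value(Y) = baseline + slope × indicator(Y−1) + noise`,
  with all slopes 0 by default (a true null for calibration tests) and
  per-descriptor baselines/noise at field-plausible magnitudes (e.g.,
  total catch ≈ 25 ± 5 per net night, relative weights ≈ 90 ± 4).

What the generator does **not** emulate: spatial heterogeneity of
temperature and DO (one profile applies lake-wide, the same implicit
assumption the analysis makes), inflow/outflow hydrodynamics, metabolism
or biogeochemistry, and observation error in bathymetry. Tests passing
on this lake show the *machinery* is correct and calibrated; they do not
validate the limnology of any real reservoir.

## Problem sizes and runtime choices

The test suite runs a 12×12-cell, 2-year lake for module tests and a
50×50-cell, 26-year lake (≈ 9,500 days) for end-to-end checks; the
statistical calibration suites use 500 replicate null screens, 200
replicate GAM null fits (3 simulated years each), and 200-replicate
power checks — sizes at which Monte-Carlo error is comfortably inside
the asserted bands. Exact-geometry oracles run on hundreds of random
grids up to 10×10 with random nodata masks. `scripts/acceptance.R`
re-runs the 26-year default lake from scratch.

## Known limitations

* Gaussian GAM errors on a response bounded below at zero (kept
  deliberately; the strictest range spends long runs exactly at the
  bound, which the seasonal smooth accommodates but a bounded-response
  family would model more faithfully).
* The hypsometric curve ignores perched or disconnected basins: any
  cell below the plane counts, connected to the main pool or not.
* No habitat is counted below 10 m, even in winter when deep water may
  be suitable — the analysis targets the summer squeeze, so annual
  minima are unaffected, but absolute winter volumes are conservative.
* The survey-to-indicator pairing (year Y vs Y−1) is a convention;
  `align_survey_to_indicators(lag = )` exposes it.
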