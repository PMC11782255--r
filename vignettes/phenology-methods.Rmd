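---
title: "Degree-day phenology models for black cutworm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day phenology models for black cutworm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoflight)
```

## The modelling problem

Black cutworm (*Agrotis ipsilon*) adults migrate into temperate production
regions each spring, lay eggs, and produce a larval generation whose early
instars are the window for effective insecticide applications. Management
therefore needs two linked predictions: *when do migrant adults arrive* (so
degree-day accumulation for the resident generation can start at a defensible
biofix), and *how much physiological time does each life stage need* (so the
presence of eggs, small larvae, large larvae and pupae can be projected onto
the calendar). `phenoflight` implements both halves as a single tested
pipeline: thermal-biology estimation from rearing data, flight-curve modelling
from trap networks, data-driven biofix selection, validation, and stage
forecasting.

## Degree days

All three daily degree-day methods are horizontal-cutoff formulations: a
diurnal temperature curve is assumed, truncated at the lower developmental
threshold (LDT), optionally capped at an upper threshold (UDT), and the area
above the LDT over one day is the daily value.

* **Simple average**: the curve is a constant at the daily mean, so the value
  is `max((tmin + tmax)/2 - ldt, 0)`. The mean is computed first and truncated
  after; we do not substitute the threshold for sub-threshold temperatures
  before averaging, which matches the plain reading of "simple average".
* **Single triangle**: a symmetric triangle from `tmin` up to `tmax` and back.
  With the threshold inside the diurnal range the area is
  `(tmax - ldt)^2 / (2 (tmax - tmin))`.
* **Single sine** (Baskerville–Emin): a sinusoid with mean `(tmin + tmax)/2`
  and amplitude `(tmax - tmin)/2`; with `theta = asin((ldt - Tm)/alpha)` the
  value is `((Tm - ldt)(pi/2 - theta) + alpha cos(theta)) / pi`.

An upper threshold is applied through the identity
`max(min(T, udt) - ldt, 0) = max(T - ldt, 0) - max(T - udt, 0)`, i.e. the
capped area is the uncapped area above the LDT minus the area above the UDT.
This gives a single exact implementation for all three methods. The default is
no UDT: in the temperate regions these models target, days hot enough for an
upper cutoff to matter are rare, and the species' upper threshold is not
reliably known.

Every method is property-tested against brute-force trapezoid integration
(10^5 steps) of its assumed diurnal curve over randomly drawn
(tmin, tmax, ldt) triples, to within 1e-6 degree days. Accumulation starts on
a configurable day of year (1 January = day 1, leap years use the calendar
day of year); missing days inside the accumulation window raise an error
rather than being imputed, because silently skipped days would bias every
downstream quantity.

## Thermal thresholds and constants from rearing data

Within the linear range of the thermal performance curve, development rate
*y* = 1/days increases linearly with temperature. Ordinary least squares of
per-specimen rates on rearing temperature gives intercept *a* and slope *b*,
from which

* lower developmental threshold *t* = −*a*/*b* (where the rate extrapolates
  to zero),
* thermal constant *k* = 1/*b* degree days,
* SE(*t*) = (*ȳ*/*b*) sqrt( *s*²/(*N ȳ*²) + (SE(*b*)/*b*)² ), with *s*² the
  residual mean square and *ȳ* the mean rate,
* SE(*k*) = SE(*b*)/*b*².

The regression uses individual specimens, not temperature means, so specimen
variability propagates into the standard errors; the closed-form SEs are
verified in the test suite against a 10,000-resample nonparametric bootstrap
(agreement within 20%). Rearing temperatures at which no specimen completes a
stage are excluded automatically with a message — they sit outside the linear
range (in practice this happens at temperatures that are above the threshold
yet unsurvivable, e.g. complete larval mortality at 12 °C in cutworm rearing).
A fitted slope that is not positive is returned flagged
(`status = "nonphysical_slope"`) rather than silently accepted.

Two estimators sit on top of the per-stage fits. `pooled_ldt()` averages the
threshold estimates across stage-by-diet cells (unweighted, with the SE of the
mean); pooling over cells rather than stages alone was chosen because the
cell-level fits are the atomic estimates, and the function accepts any vector
of thresholds if a different pooling is wanted. `thermal_constant_fixed_ldt()`
standardises degree-day requirements across stages and diets at one adopted
threshold: each completed specimen contributes days × (T − LDT), and the
requirement is the pooled per-specimen mean with its SE — the simplest
estimator consistent with reporting a mean ± SE per stage.

## The flight model

Weekly trap counts per site-year are converted to the cumulative proportion of
the seasonal total, placed on the accumulated degree-day axis of their site,
and pooled. Site-years whose seasonal total does not exceed 20 captures are
excluded (strictly greater than 20): sparse seasons contribute almost no
information about curve shape, and the boundary is implemented and tested
exactly.

The model for cumulative proportion *Y* at accumulated degree days *x* is

$$Y_{ij} = \frac{a}{1 + e^{-(x_{ij}-b)/c}} + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N\!\left(0,\; \sigma^2 |v_{ij}|^{2\delta}\right)$$

with *a* the upper asymptote, *b* the degree-day accumulation at half-asymptote,
*c* a growth-rate parameter, and *v* a variance covariate that lets residual
spread differ across years. This orientation — *Y* increasing in *x*, *b* the
half-rise point — is the only one under which the parameters carry their
stated meanings for a cumulative curve.

Estimation is direct maximisation of the Gaussian log-likelihood: σ is
profiled out analytically, and (*a*, *b*, *c*, δ) are optimised (log scale for
*a* and *c*) by Nelder–Mead from several starts derived from the empirical
25/50/75% crossing points of the data, followed by a BFGS polish; the best of
the runs is kept. With `fix_delta = 0` the criterion reduces exactly to
ordinary nonlinear least squares, and the test suite requires agreement with
an independent `stats::nls()` fit to optimiser tolerance. The parameter
covariance comes from the numerical Hessian of the full (non-profiled)
likelihood on the natural scale. Non-convergence is an explicit error; inside
the model grid search failures are recorded per candidate instead of aborting.

Two details deserve note. First, the choice of variance covariate: with raw
calendar years (≈2000), |v|^2δ is nearly constant over a study period, so δ is
weakly identified and mostly absorbed by σ; with a year *index* (1, 2, …) it is
a meaningful within-study heteroskedasticity parameter. The covariate is
therefore configurable (`"year"`, `"index"`, or any numeric vector), with raw
year as the default for fidelity to how such variance structures are usually
written. The package's simulations use the index form, under which
σ = 0.05, δ = 0.5 produce visit-level noise standard deviations of 0.05–0.16
across a ten-year study — a realistic range for cumulative trap proportions.
Second, *a* is not constrained to 1 during fitting; a post-fit check flags
implausible asymptotes, and `median_flight_gdd()` refuses curves with
*a* ≤ 0.5.

The median flight is the closed-form 0.5 crossing
*x*₀.₅ = *b* − *c* ln(*a*/0.5 − 1), cross-checked in tests against bisection
root-finding. Its interval is a parametric bootstrap from the (a, b, c)
covariance (2,000 seeded draws; draws whose curve never reaches 0.5 are
discarded). A bootstrap was preferred over the delta method because the
crossing is a nonlinear function of the parameters and its sampling
distribution is visibly asymmetric in practice.

## Biofix selection and validation

`grid_search_biofix()` fits and scores one model per combination of
degree-day method and accumulation start day. The default grid is
`seq(5, 125, by = 5)` — 25 start days from early January to 5 May inclusive,
times three methods, 75 candidate models. Scores are MAE, RMSE and pseudo-R²
(1 − SS_res/SS_tot) pooled over all visit points; the best candidate per
method is the lowest MAE, with ties broken by lower RMSE and then the earlier
start day. Because the cumulative proportions do not depend on the candidate
start day, daily degree days are computed once per method and only re-masked
and re-summed per candidate, which keeps the full grid to a few seconds.

`year_split_cv()` validates a chosen candidate by splitting *years* (not
site-years) into train and test sets — the year is the natural replication
unit for a migration-driven process. The split fraction is 50/50 by default
and seeded. The fitted training model predicts test proportions at their
observed degree-day values, and observed values are regressed on predicted
(direction configurable): slope near 1 and intercept near 0 indicate
calibrated predictions. Passing identical train and test year sets reproduces
the in-sample scores exactly, which the tests assert.

## Stage forecasting

`project_stage_windows()` accumulates degree days from a biofix date
(inclusive) and reports the first date on which each stage's cumulative
checkpoint is reached. With constant accumulation *d* per day, checkpoint *q*
is reached on day ⌈*q*/*d*⌉, counting the biofix date as day 1. Three presets
encode thermal requirements at LDT 9.8 °C: `"combined"` (diets pooled; egg
75.72 DD, small larvae +142.16, large larvae +230.28, pupae +186.67, with the
independently estimated one-generation total of 648.47 DD reported alongside),
`"ryegrass"` (egg 75.72, larvae 315.92, pupae 178.64, generation 601.98), and
`"artificial"` (egg 75.72, larvae 384.08, pupae 193.22, generation 658.71).
The generation total is *not* the sum of the stage increments — each is
estimated on its own specimens — so both are exposed rather than forcing
consistency. The biofix is used as supplied (typically the predicted median
flight date); any oviposition lag is left to the caller because the delay
between arrival and egg-laying is not separately estimable from trap data.
If the weather record ends before a checkpoint, the forecast is returned
truncated with a warning rather than failing.

## Synthetic data: what it emulates and what it does not

The generators exist so that every stage of the pipeline can be exercised and
calibrated without field data.

* `gen_weather()`: daily means follow a sinusoid peaking in mid July
  (defaults: annual mean 11.5 °C, amplitude 8 °C — a maritime Pacific
  Northwest regime), plus a per-site-year offset (sd 1 °C, interannual and
  siting variability) and daily noise (sd 2 °C); tmin/tmax sit half the
  diurnal range (10 °C) below/above the mean, so `tmin <= tmax` by
  construction.
* `gen_trap_counts()`: expected cumulative proportions from the logistic
  (defaults a = 1, b = 270 GDD, c = 30 GDD on a single-sine, LDT 9.8,
  start-day-120 axis), per-visit Gaussian noise scaled σ|v|^δ
  (σ = 0.05, δ = 0.5 on the year index), clamped to [0, 1] and made monotone,
  then weekly increments scaled by an expected seasonal total of 200 and
  realised as Poisson counts. `count_model = "expected"` skips the Poisson
  step so noiseless data lie exactly on the logistic.
* `gen_dev_times()`: rates (T − t)/k plus specimen noise (sd 0.002 day⁻¹,
  redrawn if non-positive), five temperatures (12–32 °C), two diets, with
  12 °C designated a complete-mortality temperature.

Two features of real data are deliberately not emulated: trap counts are not
overdispersed beyond Poisson (real funnel-trap counts often are), and the
count realisation itself (clamping at 0 and 1, forced monotonicity, integer
rounding) makes realised cumulative proportions deviate from the pure Gaussian
model — biasing the fitted midpoint slightly early. Tests that check
*estimator calibration* (confidence-interval coverage) therefore draw data
from the Gaussian model itself, while a separate end-to-end test checks that
the full count pipeline still recovers the curve midpoint within 5 GDD at 100
site-years. Passing both says the estimator is correct under its assumptions
and robust to realistic count realisation; it does not certify behaviour under
trap failures, multi-peaked flights, or species misidentification.

## Numerical choices and problem sizes

* Optimiser: Nelder–Mead (reltol 1e-12, up to 2000 iterations) from up to four
  empirical starts, then BFGS; δ search is unconstrained with σ profiled in
  closed form; the profiled variance is floored at 1e-20 so zero-residual fits
  remain finite.
* Ties in the biofix search break deterministically (MAE, RMSE, earlier DOY).
* All serialised floating-point output uses 6 significant digits, and every
  random component (generators, year splits, bootstraps) is seeded, so
  repeated runs are byte-identical.
* Test and simulation sizes were chosen as the smallest that make the
  properties sharp: 100 replicates of 40 site-years for fit recovery and
  coverage, 50 replicates of 12 site-years (σ = 0.02, the strong-signal
  regime) for biofix-selection stability, 1000 random triples for degree-day
  oracle equivalence, and 10,000 bootstrap resamples for the SE comparison.

## Known limitations

* The rate regression assumes linearity over the observed temperature range;
  no curvilinear (e.g. upper-threshold) development model is provided, so
  extrapolation above the warmest rearing temperature is unreliable.
* The logistic model describes one flight wave; strongly bimodal seasons
  (separate migration pulses) will be summarised by a compromise curve.
* Cumulative-proportion points within a site-year are treated as independent
  by the likelihood, as is conventional for this model family; the year-level
  variance power absorbs some but not all of the induced correlation.
* Forecast presets are specific to LDT 9.8 °C; supplying a different LDT with
  the preset checkpoints would silently mix scales, so custom checkpoints
  should accompany custom thresholds.
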