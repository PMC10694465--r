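---
title: "Projecting heat-stress labor losses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting heat-stress labor losses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwhl)
```

# The problem

Occupational heat stress reduces work capacity: above a worker-specific
heat threshold, a growing fraction of each work hour is lost to rest,
slower pacing and safety breaks. Projecting this burden over a warming
century needs four linked pieces: a heat-stress index computable from
daily climate-model output (wet bulb globe temperature, WBGT), a mapping
from WBGT to the fraction of a work hour lost (the exposure--response
function, ERF), the spatial distribution of the workers actually exposed
(by sector, indoor/outdoor setting and air-conditioning access), and an
accounting framework that turns these into work hours lost (WHL),
attributes changes to drivers, and prices the avoidable part.

`heatwhl` implements this chain end to end. Because the real inputs
(bias-corrected regional climate simulations, kilometre-scale population
products, statistical-yearbook employment shares) are large and not
redistributable, the package ships a synthetic-data generator that
emulates their structure with known ground truth, so every stage is
testable and the whole pipeline runs in seconds.

# WBGT from daily meteorology

**Indoor.** The simplified WBGT regression uses only air temperature and
humidity:
$$\mathrm{sWBGT} = 0.567\,T_a + 0.393\,e + 3.94,$$
with vapor pressure $e$ (hPa) from the Magnus form
$e = (\mathrm{rh}/100)\,6.105\exp\!\big(17.27\,T_a/(237.7+T_a)\big)$.
This is the standard two-variable indoor approximation in the
heat--labor literature; it is known to run slightly warm in humid
conditions. The estimator is applied to both the daily mean and the
daily maximum temperature to give daily mean and max indoor WBGT.

**Outdoor.** The outdoor index adds wind and solar radiation through the
classical composition $\mathrm{WBGT} = 0.7\,T_{nwb} + 0.2\,T_g +
0.1\,T_a$. The globe temperature $T_g$ solves a spherical energy balance
(absorbed shortwave $= 0.25\cdot 0.95\cdot S$ against convective loss
$6.3\,u^{0.6}(T_g-T_a)$ and longwave exchange), by Newton iteration with
tolerance $10^{-8}\,$°C; the equation is increasing and convex in
$T_g$, so the iteration is globally safe, and non-convergence (never
observed) raises an error naming the cells. The natural wet-bulb is the
Stull (2011) psychrometric wet-bulb regression plus a radiation
correction $0.25\,(T_g - T_a)$, mirroring the behaviour of full
natural-wet-bulb models: no sun collapses it to the psychrometric value,
strong sun or calm air raises it. The estimator is monotone increasing
in radiation and non-increasing in wind under sun, and $T_g \to T_a$ as
wind grows. The backend is pluggable (`outdoor_wbgt(..., backend=)`) so
a different published estimator can be substituted. Indoor workplaces,
where a wind term would be needed, are treated with the two-variable
regression instead; the conventional fixed 1 m/s indoor wind assumption
is therefore never exercised numerically.

Because the two estimators carry different biases, the indoor regression
can locally exceed the outdoor composition by several degrees on cool,
humid, overcast days. Consequently the expectation that heavy outdoor
work loses more hours than light indoor work holds robustly in grid
aggregates and in warm cells, but not cell-day by cell-day; the tests
assert it at the aggregate level.

**Hourly disaggregation ("4+4+4").** Climate projections are daily, but
losses accrue by hour. A 12-hour daylight block (07:00--19:00) is
approximated with 4 h at the daily max, 4 h at the max/mean midpoint
and 4 h at the daily mean, assigned symmetrically around 13:00:
11:00--15:00 max, 09:00--11:00 and 15:00--17:00 midpoint, 07:00--09:00
and 17:00--19:00 mean; hours outside the block carry the daily mean.
The clock assignment is a documented convention, not a physical claim.
The 8-hour workday defaults to 08:00--12:00 and 13:00--17:00 (so one
mean hour, four midpoint hours, three max hours); `workday_def(delay =
1)` or `delay = 2` shifts the whole window later, the two standard
sensitivity settings for postponed schedules. Which 8 daylight hours
workers occupy is genuinely unknowable from daily data, so both the
layout and the workday are configuration.

# The exposure--response function

The loss fraction at a given WBGT is a normal CDF,
$$\mathrm{Loss}(w) = \tfrac12\Big[1 + \mathrm{erf}\Big(\frac{w -
\mathrm{Prodmean}}{\mathrm{Prodsd}\sqrt 2}\Big)\Big],$$
with one $(\mathrm{Prodmean}, \mathrm{Prodsd})$ pair per metabolic-rate
class: 200 W (light work — service), 300 W (moderate — manufacturing),
400 W (heavy — agriculture and construction). Physically sensible sets
satisfy $\mathrm{Prodmean}(400) \le \mathrm{Prodmean}(300) \le
\mathrm{Prodmean}(200)$; the constructor warns when violated.

**Fitting.** `fit_workrest_cdf()` fits each intensity's curve to a
work/rest table by bounded Levenberg--Marquardt least squares on the
loss scale ($\mathrm{loss} = 1 - \mathrm{work\ fraction}$, reading the
recommended work/rest ratio as work time over cycle time).
Initialization is taken from the data — the mean from the point nearest
loss 0.5, the sd from half the span between the points nearest losses
0.16 and 0.84 — with $s$ bounded to $(0.1, 20)$ °C. Tables need at
least 4 distinct WBGT points per intensity; degenerate tables (constant
work fraction) are rejected. On noiseless CDF-generated tables the fit
recovers the generating parameters to $10^{-6}$; with 2% noise on 9
points the mean absolute error in the mean stays well under 0.5 °C
(both properties are in the test suite).

**Calibration.** Occupational work/rest standards encode local heat
sensitivity but were designed to limit core temperature, not to measure
output loss; epidemiological curves measure output loss but only exist
for the 300 W class. The two are combined by a two-step transfer: fit
all three intensities to the standard, then adopt the epidemiological
300 W anchor exactly and shift the 200/400 W curves by the
standard-fit parameter differences, componentwise in mean and sd
(`calibrate_chinese_erf()`). Whether the sd offsets should transfer or
the anchor sd should apply everywhere is not determined by the source
material; difference transfer is the default with `sd_mode = "anchor"`
as the alternative. Transfers that would produce a non-positive sd are
an error. The parameter sets shipped by `default_erf_inputs()` are
synthetic stand-ins with the right structure; tests depend only on the
machinery, never on those values.

# Exposed working population

Gridded total population is split by province-year rates: agricultural
workers are rural population times the agricultural employment rate,
non-agricultural workers are urban population times the
non-agricultural rate, divided into construction, manufacturing and
service by a per-province split (default 0.15/0.35/0.50, configurable —
yearbook-style shares are not public at this granularity). Employment
rates are held constant over time, so the worker trajectory is driven
entirely by total population and urbanization. Air conditioning
protects indoor workers only: manufacturing and service counts are
scaled by $1 - \text{AC rate}$ (default 0.6, the approximate current
household penetration level); future-adoption scenarios are linear
ramps to 0.7/0.8/0.9 by 2100 (`ac_rate_path()`). A single national
rate is used; a per-province path can be passed instead. Analysis-grid
aggregation (`regrid()`) sums population (mass conserving to machine
precision) and averages WBGT, and only supports exactly nesting grids —
general resampling is deliberately out of scope.

# Work hours lost, aggregation, attribution, benefits

Daily per-capita WHL is the sum of the loss fraction over the 8 work
hours; annual values sum over a 365-day no-leap calendar (the common
climate-model convention, which also simplifies annual bookkeeping).
Total WHL is per-capita times exposed workers, per cell and sector;
provincial and national aggregates are exact sums, so additivity holds
to machine precision and provincial proportions total 100%. Every
calendar day is a potential workday: this matches the full-time-job
conversion 1 job = 8 h × 365 d = 2920 h/yr used for headline
equivalences (32.1 and 8.5 billion hours convert to 11 and 3 million
jobs). Ensembles are summarized by the member mean; with only a few
pseudo-GCM members the 95% interval is reported as the ensemble
min--max (the `"normal"` option gives a parametric interval instead).
Per-capita national WHL divides by the exposed working population.

**Attribution.** `factor_separation()` evaluates the WHL functional at
the four corners of (climate state) × (population state): the climate
effect is the change with population held at the reference, the
population effect the converse, and the interaction the remainder —
additive by construction, zero for separable evaluators. The reference
state is the first period of the comparison.

**1.5-degree benefit.** No scenario tracks 1.5 °C exactly, so the
`cool15` synthetic scenario stands in: generated like the low-emission
pathway but with the trend stabilizing at 2035, emulating the standard
identification of the early-century low-emission window with the
1.5 °C world. Avoided WHL at mid-century (2051--2070) substitutes only
the WBGT difference between an RCP scenario and `cool15` into the ERF,
holding population at its period average. Cells where the RCP is
locally cooler contribute negatively; they are counted and kept by
default (`truncate_negative = TRUE` zeroes them). The economic value is
the exact product of avoided hours and a configured unit value of a
work hour (scalar or per-province) — the human-capital convention.

# The synthetic study domain

The generator emulates the structure of the real inputs, not their
values:

* **Climate.** Temperature is a latitudinal gradient (annual mean
  ~22 °C at the southern edge, −0.6 °C per degree latitude) plus a
  seasonal cycle peaking in mid-July (amplitude 7--10.75 °C, larger
  toward the north), a scenario trend, and AR(1) daily noise
  (autocorrelation 0.7, marginal sd 2 °C — plausible daily weather
  persistence). Scenario trends are 0.2 °C/decade flattening after
  2050 (`rcp26`), 0.35 (`rcp45`), 0.5 (`rcp85`), and 0.2 flattening
  after 2035 (`cool15`). Daily max exceeds the mean by a seasonal
  3--5 °C half-range; humidity is anticorrelated with the temperature
  anomaly at −1 %/°C and clipped to [0, 100]; wind and radiation are
  non-negative with their own noise. Pseudo-GCM members get
  independent noise streams and evenly spaced multiplicative trend
  perturbations (±8%) — nothing here claims fidelity to real
  inter-model spread, whose statistical structure is not documented in
  the source material.
* **Population.** The national total follows an asymmetric bell peaking
  at 0.75 billion in 2030 (slow rise before, gentler ~30% decline by
  2100), split across rectangular toy provinces by fixed random shares
  and within provinces by fixed random cell weights — so province
  totals are conserved on the grid by construction. Urbanization rises
  logistically from ~0.45 toward ~0.85; fertility variants scale the
  total by ramps reaching 0.85 (low) and 1.10 (high) in 2100.
* **Work/rest tables** are generated from known ERF parameters plus
  optional noise, making parameter recovery an exact oracle.

What passing tests on this domain show is that the machinery is
correct: conservation, monotonicity, closed-form values, parameter
recovery, scenario ordering and trend directions. What they cannot show
is fidelity to any real region: real WBGT fields have spatial
covariance, topography and humidity regimes the generator does not
attempt, and real employment structure varies in ways the constant
rates do not capture.

# Problem sizes and numerical choices

The standard experiment used by the tests and the acceptance script is
an 8 × 8 grid (64 cells), three provinces, 2 pseudo-GCM members, and
years 1986--2100 sampled every 5th year — about half a million
cell-days per scenario, which keeps a four-scenario run around a
quarter of a minute while leaving all qualitative behaviour (scenario
ordering, upward rcp85 trend against a declining workforce, benefit
ordering) intact. Other choices worth knowing: WBGT grids are
equal-area by construction so area-weighted means are plain means;
the Newton solve for globe temperature starts from the linearized
balance and converges in a handful of iterations; fits are rejected
rather than silently extrapolated when a table is degenerate; and all
randomness flows from a single integer seed through deterministic
per-scenario, per-member offsets, so identical configurations are
bit-reproducible.

# Limitations

Beyond the synthetic-domain caveats above: the indoor estimator's warm
bias relative to the outdoor composition can locally invert the
indoor/outdoor loss ordering on cool overcast days; the hourly layout
and workday window are conventions; employment rates and the sector
split are frozen in time; migration, employment-rate change and
acclimatization are not modelled; and the ERF stand-in parameters are
placeholders until replaced by fitted standards and a published anchor.

# A worked micro-example

```{r example}
inputs <- default_erf_inputs()
standard <- fit_workrest_cdf(generate_workrest_table(inputs$standard))
params <- calibrate_chinese_erf(standard, inputs$anchor300)
as.data.frame(params)

cfg <- synth_config(grid_shape = c(4, 4), years = seq(1990, 2090, 25),
                    scenario = "rcp85", n_pseudo_gcms = 2, seed = 1)
ens <- generate_climate(cfg)
pin <- generate_population_inputs(cfg)
exposed <- apply_ac_adjustment(working_population(pin$pop, pin$rates), 0.6)
res <- project_whl(ens, exposed, params)
national_whl_series(res)
```
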