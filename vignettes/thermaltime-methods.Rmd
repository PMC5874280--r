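---
title: "Reconstructing diurnal temperature and thermal time: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing diurnal temperature and thermal time: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaltime)
```

## The problem

Degree-day sums computed from hourly temperature are more faithful to
organism development than sums computed from daily means, because the
`max(0, T - T_b)` clamp interacts with the diurnal cycle: a day whose mean
sits below the base temperature can still accumulate thermal time during
warm afternoon hours. Long station records and essentially all gridded
climate products, however, carry only daily minima and maxima. The package
therefore reconstructs the diurnal course from Tn/Tx and runs the
degree-day machinery on the reconstruction.

## The diurnal model and its assumptions

The day is divided at three anchor points expressed in true solar time
(TST): sunrise `h_R`, sunset `h_S` (both from the site latitude and day of
year), and the two lags `c` and `a` that place the daily minimum at
`h_R + c` and the maximum at `(h_R + h_S)/2 + a`. Between minimum and
sunset the curve is a sine arc through both extremes; at night it is an
exponential relaxation from the sunset temperature towards the *next*
minimum — the one of day `i` before sunrise, the one of day `i + 1` after
sunset — over the corrected night length (`n1 = h_R,i - h_S,i-1 + c + 24`,
`n2 = h_R,i+1 - h_S,i + c + 24`).

Two structural choices matter:

* **Force-through night correction.** The raw exponential does not reach
  `T_n` exactly at `h_R + c`. A linear correction term `-(t/n) e^{-b}`
  closes the gap, and we scale it by the amplitude `(T_S - T_n)` so the
  force-through is exact for any amplitude. The unscaled variant is
  available as `night_form = "literal"` for comparison; it leaves a
  residual of order `e^{-b}` degrees at the minimum and breaks the
  branch-continuity identities, which is why the scaled form is the
  default.
* **Cross-day coupling.** Because the evening branch targets tomorrow's
  minimum with the same night length that tomorrow's morning branch uses,
  midnight continuity holds *algebraically*; the test suite checks it to
  1e-9 °C over multi-year series. A consequence worth knowing: daily
  reconstructed extremes are not confined to `[T_n, T_x]` of their own
  day. After a warm day, the first hours of a cold day stay warmer than
  its `T_x`; before a cold day, late evening can drop below the current
  day's `T_n`. This is physical, intended behaviour, not leakage.

The model assumes one minimum near sunrise and one maximum in the early
afternoon. Days that violate this — frontal passages, föhn, overcast days —
are exactly the days the clear-sky screen removes from calibration, but
they remain in any evaluation or degree-day computation.

## Solar geometry

Declination and the equation of time use Spencer's Fourier expansions
(declination accurate to < 0.3°, equation of time to < 1 min), sunrise and
sunset come from the hour-angle relation `cos H = -tan(lat) tan(decl)`
without refraction or horizon corrections, and mean local time converts to
TST by the longitude offset (4 min per degree from the standard meridian)
plus the equation of time. At this accuracy the downstream timings shift
by well under the hourly sampling step. "Potential" daily radiation — the
denominator of the clear-sky ratio — is daily extraterrestrial radiation
times a constant clear-sky transmissivity, default 0.75. The transmissivity
is a free knob, not an atmospheric model: only the *ratio threshold* (0.9)
is scientifically meaningful, and both are configurable in
`clear_sky_criteria()`.

## Calibration

`fit_parameters()` maximises the modified index of agreement (the
absolute-deviation Legates–McCabe form, exponent 1) between observed and
reconstructed hours, pooled over all hours of the calibration days, with
Nelder–Mead search started from the mean site-specific triple
(2.79, 3.16, 0.79). Per-day averaging of the objective is available
(`pooling = "per_day"`) but the pooled form is the default: it is simpler,
never empty, and weighs each hour equally. Simplex settings default to a
relative objective tolerance of 1e-6 with at most 2000 iterations; because
the minimised quantity `1 - MIA` approaches zero at a perfect fit, the
stopping rule tightens automatically near the optimum, and noise-free
closed-loop tests recover generating parameters to 1e-3 or better.

Decisions where the procedure was genuinely open, and what we chose:

* "Noon" in the minimum-before-noon rule is TST noon (`h = 12`) — the rest
  of the pipeline runs in TST, and civil noon would re-import the
  longitude offset the TST conversion just removed.
* Calibration years are sampled *without* replacement (`n_years` distinct
  years), seeded; sampling with replacement would silently duplicate
  hours and overweight years.
* The pooled "generic" fit concatenates the stations' hours rather than
  averaging per-station objectives, so big stations carry proportionally
  more weight, matching the pooled-days reading of a multi-site
  calibration.
* Fits with `a > 5.5` h are flagged `realistic = FALSE` but not clipped:
  such timings do occur at high-alpine or otherwise irregular sites and
  should be visible, not hidden.

One property of the MIA objective deserves emphasis: it is an L1-type
criterion, so a pooled fit over sites with different true parameters tends
to settle *at* the parameters of one contributing site (median behaviour)
rather than at a variance-weighted average. The tests assert the pooled
optimum lies in the closed interval spanned by the site values and beats
both endpoints' objectives, which is what L1 optimality actually
guarantees.

## Degree-days, correction, efficiency

`agdd()` implements the hourly clamp sum divided by 24, per day of year,
cumulatively; days with more missing hours than `max_missing_frac` are
excluded and flagged rather than imputed. The empirical correction factor
is the mean over site-years of the actual/estimated end-of-year ratio
(ratio-of-means available as an option; the two differ only in how
site-years are weighted), applied multiplicatively to the whole cumulative
series — the smallest structure that removes a systematic end-of-year
bias while preserving monotonicity, so threshold dates can only move one
way (a factor below 1 delays them). Threshold dates use the non-strict
convention (the first day whose cumulative sum *reaches* the threshold
counts). The efficiency statistic excludes site-years where either series
never reaches the threshold from its denominator and reports them
separately; including them as automatic failures would conflate model
error with climatological impossibility. Leap years accumulate through
DOY 366 and anchor the end-of-year ratio at their actual last day.

## The synthetic generator

`generate_station()` exists so that every stage is testable with known
ground truth. It layers, in order: a seasonal sinusoid (defaults: annual
mean 9 °C, amplitude 9 °C peaking at DOY 200, diurnal range 8 ± 3 °C —
a Swiss-plateau lowland profile); AR(1) day-to-day noise (phi = 0.6,
marginal SD 1.5 °C) independently on Tn and Tx; the diurnal model at the
configured true parameters; i.i.d. Gaussian hourly noise (SD 0.5 °C); and
a Bernoulli 30% of overcast days whose amplitude is flattened (factor
0.4), whose hourly profile is usually time-reversed so the minimum falls
in the afternoon, and whose radiation ratio is drawn below the 0.9
clear-sky threshold (clear days draw above it).

What it emulates: the statistical texture needed to exercise every code
path — seasonal cycles, weather persistence, irregular days that the
clear-sky screen must reject, elevation structure via a constant lapse
rate on grids. What it does not: fronts and persistence beyond AR(1),
radiation physics, humidity, real topography. Passing tests therefore
demonstrate the *machinery* — identities, recovery, screening, pipeline
consistency — not skill on real station data, which must be assessed
against observed records.

A subtlety that mirrors reality: with day-to-day noise active, some
non-overcast days acquire genuine evening minima (the next day is much
colder), so the clear-sky screen correctly passes fewer than the nominal
70% of days. Property tests that need an exact ground-truth fraction
therefore silence the day-to-day noise; the default configuration is
tested structurally instead (every overcast day excluded, most regular
days retained).

## The spatial stage

`map_threshold_dates()` runs the station pipeline per cell and year —
solar times from the cell's own latitude, since the model operates in TST
and longitude offsets cancel — then reduces to the mean threshold DOY,
its inter-annual SD and the count of years reached. Cells are processed
independently and results are invariant to processing order. The generic
degree-day correction (0.974) is applied by default and can be disabled.
Cells above 1500 m a.s.l. are flagged: generic lowland calibrations are
not trustworthy in high-alpine thermal regimes. Grids move through NetCDF
(`ncdf4`) or long-format CSV; raster formats beyond that are out of scope.

## Numerical choices and degenerate inputs

* Hour grid: continuous decimal TST internally; the sampling grid defaults
  to 1..24 so that a day's 24 values are exactly the ones its degree-day
  sum consumes, with `h = 24` the following midnight. `h = h_S` belongs to
  the day branch (non-strict upper bound).
* Degenerate daylength (`h_S <= h_R + c`) and non-positive night lengths
  raise errors rather than extrapolate; they cannot occur for sensible
  mid-latitude parameters.
* Series edges use same-day surrogates for the absent neighbour and flag
  the day `"edge"`; interior days with missing Tn/Tx yield missing hours
  (no imputation) and their neighbours fall back to the edge rule.
* Polar day/night raises an explicit error in `sunrise_sunset()` (the
  intended domain is mid-latitude agriculture).
* Parameter sanity bounds (`-2 < a < 6`, `b > 0`, `-2 < c < 4`) reject
  nonsense early; the optimiser treats excursions outside the box as very
  poor fits rather than errors.

## Problem sizes used in checks

The shipped tests and the acceptance script run entirely on generated
data: stations of 1-4 years (365-1461 days, 24 hourly values each),
calibration sets of a few hundred to ~2000 days, 20-replicate noise
studies, and grids up to 5 x 10 cells x 3 years. These sizes keep the
full suite in the low minutes on one CPU while leaving every statistic
well inside its asymptotic regime; all of them scale linearly if larger
studies are needed.

## Known limitations

* Skill on real data is bounded by the regular-day assumption; overcast
  and frontal days are reproduced poorly by construction, which is why
  the empirical correction factor exists.
* The afternoon-minimum phenomenon means daily records alone cannot
  disambiguate when the minimum occurred; the model always places it
  after sunrise.
* The generic parameter triple and its correction factor were calibrated
  for Swiss lowland conditions; other regions should recalibrate
  (`fit_generic()`) rather than reuse them.
* MIA-based calibration inherits L1 behaviour: robust to outlier hours,
  but pooled multi-site fits favour the dominant site rather than
  averaging.
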