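---
title: "From tag records to foraging comparisons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tag records to foraging comparisons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcaforage)
```

# The problem

Resident killer whales travel and share prey as social groups but chase and
capture salmon individually, mostly at depth where direct observation is
impossible. Archival multisensor tags (DTAG class) attached by suction cup
record depth, triaxial acceleration, orientation (pitch, roll, heading),
and stereo sound at high rates for a few hours per deployment. This package
turns those records into per-deployment foraging metrics — how often an
individual captured prey, how hard it searched, how its time was budgeted —
and compares them across populations, sexes, and demographic classes with
mixed models.

This vignette documents the model and signal-processing assumptions, the
tunable parameters and their defaults, the synthetic-data generator used
for validation, and the design decisions taken where several reasonable
choices existed.

# Dive detection and phases

A *dive* is a depth excursion exceeding 1 m bounded by surfacings shallower
than 0.5 m. Boundaries sit on the surface samples adjacent to the submerged
run, so ties at the 0.5-m threshold resolve toward the longer dive. Dives
shorter than 4 s are discarded (incomplete surfacings and pressure-sensor
flutter at high sampling rates), as are dives starting in the first 5 min
of a deployment (short-term behavioral response to tagging). All four
values are arguments of `detect_dives()` with these defaults.

Each dive is partitioned into *descent*, *bottom*, and *ascent*, the bottom
phase being the contiguous span from the first to the last sample at ≥ 70%
of the dive's maximum depth. The first-to-last rule (rather than the union
of all supra-threshold samples) guarantees exactly three contiguous phases;
a mid-bottom wiggle below the threshold stays in the bottom phase. A square
profile degenerates gracefully: its descent is one sampling interval.

# Kinematic capture signature

Three per-phase variables carry the capture signal:

* **Jerk peak** — the maximum of the jerk magnitude (Euclidean norm of the
  first difference of triaxial acceleration times the sampling rate)
  divided by the deployment-wide median jerk magnitude. The ratio (not a
  difference) makes the feature scale-free across tags and sampling rates;
  the median is taken over the whole deployment, surface periods included,
  as a robust per-tag noise floor. Both choices are configurable via the
  `median_jerk` argument of `phase_features()`.
* **Roll at jerk peak** — absolute roll (degrees) at the moment of the
  phase's jerk peak; salmon pursuit involves rapid rolling maneuvers.
* **Heading circular variance** — one minus the mean resultant length of
  the phase's heading vectors, in [0, 1]; erratic pursuit raises it. All
  phase samples are used (no decimation).

## Threshold calibration

Capture dives are classified by minimum thresholds on all three features,
met simultaneously in at least one phase (inclusive comparisons). The
"some phase" rule, rather than requiring a fixed phase, reflects that
pursuit can begin in descent and end in ascent. Thresholds are calibrated
per population against *acoustically confirmed* captures — dives whose own
audio contains both a terminal buzz and prey-handling sounds. Buzzes alone
also occur in unsuccessful pursuits, so handling sounds are required by
default (`require_handling = FALSE` relaxes this).

The calibration rule: for each confirmed dive take the phase with the
largest jerk peak as its capture phase, then set each threshold to the
componentwise minimum of the capture-phase features across confirmed dives.
These are the *largest* thresholds that still detect every confirmed
capture — sensitivity is 1.0 by construction, and the false-positive rate
is whatever the data imply, measured on the non-confirmed dives and
reported, never tuned to a target. Calibration statistics are restricted to
dives at or beyond 50 m, where confirmed and negative sets are reliable;
shallower dives are still classified. This deliberately conservative
operating point accepts false positives to guarantee a near-zero miss rate,
which is the right trade-off when capture rates of a prey-limited
population are the quantity of interest.

# Acoustic classification and time budgets

Clicks are classed by the interval to their predecessor: buzz < 11 ms,
fast 11–100 ms (both bounds inclusive — the band is written inclusively in
the field's convention), slow > 100 ms. The first click of a train inherits
its successor's class. Intervals over 2 s break a train so bout gaps are
never counted as slow intervals; an isolated click is classed slow, since
its neighbours are by definition beyond the slow cutoff. Intervals are
rounded to the nearest microsecond before comparison so that the class
boundaries are well defined under floating-point time arithmetic.

*Searching time* sums the durations of dives containing slow clicks and
nothing else (at least one slow click required — silence is not searching).
*Travel/rest time* sums silent non-capture dives shallower than 30 m.
Surface-period sounds are retained in the event stream but attach to no
dive and enter no budget. The three dive categories are disjoint by
construction, so their summed times never exceed the deployment duration.

# Tracks and bathymetry

Tags carry no GPS, so positions are dead-reckoned: each sample advances the
track by `speed * cos(pitch) * dt` along the heading, on a local tangent
plane about the origin (equirectangular projection — adequate for
deployment extents of a few km), decimated to 1 Hz. The default speed model
is a constant 1.5 m/s cruising speed, replaced per sample by the
vertical-speed heuristic `|dz/dt| / |sin(pitch)|` when |pitch| > 30°, where
depth rate constrains speed well. Accumulated drift is removed by forcing
the track through GPS fixes taken at surfacings: between consecutive fixes
the error is distributed linearly in time (exact at every fix, to < 1e-9
degrees); beyond the first/last fix a constant offset applies; a single fix
shifts the whole track.

Bathymetry at each dive start comes from the containing cell of an ESRI
ASCII grid (nearest-cell, boundary ties toward the lower index) — a single
grid value, not bilinear interpolation, because grid cells (15 arc-seconds
in typical use) exceed the residual track error.

# Foraging metrics and group summaries

Per deployment: capture count; capture rate = count / deployment hours;
efficiency = count / searching hours; proportions of deployment time in
capture dives and in travel/rest dives; capture-dive depths and
bathymetries. Efficiency is *missing* when audio could not be analyzed and
*undefined* (excluded from summaries) when searching time is exactly zero —
a tabulated 0 and a blank cell mean different things and are never
conflated.

Group summaries are unweighted means over deployments (each deployment
counts once regardless of duration) with SE = sd/√n; this is the
convention that matches per-deployment rate comparisons. Sex-based
groupings exclude the unknown-sex deployment; demographic groupings use
only adults (≥ 12 years) with known calf (≤ 3 years) or living-mother
status.

# Mixed models

Four families cover the response types: Poisson and nbinom1 (variance
`mu(1 + alpha)`, linear in the mean) for counts with a log link and an
offset — `log(deployment hours)` or `sqrt(cumulative searching hours)`,
entered with coefficient 1 exactly as specified; beta with a logit link for
time-budget proportions, optionally with a log-linear dispersion covariate;
Gaussian for log-transformed depths. Boundary proportions are compressed by
`(y(n-1) + 0.5)/n` before beta fitting. Random intercepts (at most two)
absorb week-of-year environmental variation and, for dive-level responses,
deployment identity.

## Week-of-year convention

"Week of year" is the day-of-year block convention: days 1–7 of the year
are week 1, 8–14 week 2, and so on, crossed with the calendar year
(`"2010 37"`). This is the common idiom in R ecological analyses (the
`lubridate::week()` convention) and is a pure function of the date.
ISO-8601 weeks are a defensible alternative; the two differ in how they cut
week boundaries and can shift a handful of deployments between adjacent
blocks, which moves small-sample mixed-model estimates by a few percent.

## Engines and estimation

`fit_glmm()` exposes two engines behind one interface. `glmmTMB` (Laplace
approximation, optional REML) supports all four families and dispersion
covariates and is the default for non-Gaussian fits; final reported fits
use REML, which reduces the small-sample downward bias of variance
components that plain ML incurs with a dozen random-effect levels.
`lme4` provides Gaussian REML fits with up to two crossed intercepts and
Poisson fits by adaptive Gauss–Hermite quadrature (default 9 nodes; the
log-likelihood is stable to < 1e-4 between 9 and 15 nodes at this data
scale). In the zero-variance limit both collapse to the fixed-effects-only
GLM, which the test suite asserts to 1e-6. Non-convergence is flagged on
the returned object and never silently repaired.

Random structures are selected by AIC with a delta-2 band: among candidates
within 2 units of the minimum, the fewest-parameter model wins (ties: fewer
random factors, then candidate order), and non-convergent candidates are
excluded with a warning. Fixed effects are then pruned by recursive
single-term deletion with likelihood-ratio tests at alpha = 0.05, always
refitting by ML and respecting marginality (an interaction shields its main
effects). Pairwise level comparisons use estimated marginal means on the
link scale with single-step multivariate-t ("Tukey") adjustment.
Overdispersion of count fits is checked by a plug-in parametric bootstrap:
the observed Pearson dispersion is compared to its distribution under
`n_sim` response vectors simulated from the fitted conditional means with
the family's mean-variance law (two-sided p, +1 correction).

# The synthetic deployment generator

`simulate_deployment()` produces the full record of a deployment whose
truth is known, so every stage is testable without field data. What it
emulates:

* trapezoidal dives (constant 1.5 m/s descent/ascent, flat noisy bottom) —
  the simplest geometry that exercises the 70%-of-maximum bottom rule;
* three dive types: capture dives (log-normal depths around 80 m, clamped
  ≥ 55 m so captures sit above the 50-m calibration cutoff), searching
  dives with slow-click trains only, and shallow (5–25 m) silent
  travel/rest dives;
* capture events mid-bottom-phase (pursuit happens at depth): a jerk
  transient (default 60 m/s³ against an accelerometer noise floor of
  0.3 m/s², roughly a ninefold margin over the median jerk at 10 Hz), a
  roll excursion to 90°, uniform heading jitter of ±60° across the bottom
  phase, a buzz burst around the capture, and handling sounds with
  probability 0.9;
* click trains as renewal processes with intervals uniform within each
  class band — only class membership matters downstream;
* a true track from a smoothed random-walk heading at 1.5 m/s, with GPS
  fixes every 5 min at 5 m isotropic error;
* per-deployment capture counts Poisson in the configured rate; cohort
  simulation assigns group rates (defaults: the observed population-by-sex
  means, 3.29 / 2.12 / 1.23 / 3.10 captures per hour) and takes durations
  from the deployment records.

Realized dive draws that cannot fit the deployment are trimmed from the
schedule (travel/rest first, captures last); configurations whose
*expected* load cannot fit are rejected outright. Surfacing depth noise
defaults to 0.1 m, keeping the 0.5-m surfacing criterion unambiguous; the
detected dive boundaries then sit within the threshold-crossing lag
(surface depth / vertical speed) plus two samples of the scheduled
boundaries.

What it does **not** emulate: hydrodynamics, flow noise, sound propagation,
conspecific clicks, vessel noise, tidal drift, or any correlation between
dive shape and capture success beyond the configured signature. Passing the
end-to-end recovery tests therefore demonstrates the pipeline's internal
consistency — that the detector, feature extraction, calibration, and
classification recover a known signal structure — not field-data
performance, where signature amplitudes overlap the noise floor and
acoustic confirmation is incomplete.

# Validation scales

The test suite exercises, among others: hand-computed oracles for every
signal-processing primitive (finite-difference jerk, closed-form circular
variances 0, 1, and 1 − √2/2, constructed dive profiles with known
crossings); an end-to-end cohort of 200 simulated deployments of 0.5 h at
10 Hz, requiring ≥ 95% of deployments to have exactly recovered capture
counts after pooled calibration; 200 replicate fits per model family at 48
observations in 12 week blocks, requiring ≤ 10% bias in the recovered
fixed effect; and a refit of the packaged cohort's adult-female count
model, whose coefficients are reproduced to well within ±0.05. These sizes
were chosen as the smallest that make the Monte-Carlo bounds sharp;
rerunning with larger cohorts only tightens them.

# Known limitations

* Click classification assumes the event stream contains only the tagged
  animal's clicks; separating conspecifics is upstream work.
* The calibration rule assumes at least one acoustically confirmed capture
  per population; deployments without usable audio are flagged
  uncalibratable and must borrow thresholds.
* The constant-speed dead-reckoning model biases track length during
  high-pitch maneuvers; the vertical-speed heuristic corrects the steep
  part only.
* Sensor input is CSV; NetCDF containers are not read directly.
* Beta models with two random intercepts and non-Gaussian crossed designs
  are out of scope (single-factor quadrature or Laplace only).
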