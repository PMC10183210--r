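# orcaforage

Quantifying individual foraging behavior of resident killer whales
(*Orcinus orca*) from multisensor bio-logging (DTAG-class) deployments.

Fish-eating "resident" killer whales forage in social groups but pursue and
capture salmon individually at depth. High-resolution suction-cup tags that
record depth, triaxial acceleration, orientation, and sound make those
individual prey-capture attempts observable: a capture dive carries a
transient spike in **jerk** (the rate of change of acceleration), a large
**roll** excursion, and erratic **heading** during the pursuit, while the
acoustic record carries echolocation click trains whose inter-click
intervals (ICI) grade from slow search clicks (> 100 ms) through fast
pursuit clicks (11–100 ms) to terminal buzzes (< 11 ms), and crunching
prey-handling sounds after a successful capture.

`orcaforage` implements the full analysis pipeline for such deployments:

- **Dive detection and phase partitioning** — depth excursions > 1 m bounded
  by surfacings < 0.5 m; descent / bottom / ascent phases with the bottom
  phase defined by ≥ 70% of maximum dive depth.
- **Kinematic capture classification** — per-phase jerk peak (normalized by
  the deployment median jerk), absolute roll at the jerk peak, and circular
  variance in heading, with per-population minimum thresholds calibrated
  against acoustically confirmed captures (buzz + handling sounds) at 100%
  sensitivity.
- **Acoustic time budgets** — ICI classification of click trains; searching
  time (slow-click-only dives) and travel/rest time (silent dives < 30 m).
- **Pseudotracks and bathymetry** — dead-reckoned tracks forced through GPS
  fixes, with nearest-cell bathymetry lookup from ESRI ASCII grids.
- **Foraging metrics and group comparisons** — capture rate (captures per
  deployment hour), foraging efficiency (captures per searching hour), time
  budget proportions; Poisson / nbinom1 / beta / Gaussian mixed models with
  offsets, AIC random-structure selection, likelihood-ratio term deletion,
  and Tukey-adjusted contrasts.
- **Synthetic deployments** — a generator with ground-truth dive, capture,
  click, and track labels, so the whole pipeline is testable end to end.

The count model at the heart of the demographic comparisons is, e.g. for
adult females,

```
captures_i ~ Poisson(mu_i)
log(mu_i) = beta_0 + beta_pop * SRKW_i + beta_calf * calf_i
            + log(duration_i) + b_week(i),   b_week ~ N(0, sigma^2)
```

with a week-of-year random intercept absorbing shared weekly environmental
variation (notably salmon availability).

## Worked example

The package ships a deployment summary table of 52 DTAG deployments on
Northern (NRKW) and Southern (SRKW) Resident killer whales:

```r
library(orcaforage)
d <- dtag_deployments()
validate_cohort(d)
#> Cohort of 52 deployments, 186.8 h total
#>         F  M unknown
#>   NRKW 11 18       1
#>   SRKW 10 12       0

m <- metrics_from_table(d)
group_means(m, d, "population_sex")
#>    group  n     mean        se    median
#> 1 NRKW F 11 3.289666 0.5810578 2.6041667
#> 2 NRKW M 18 2.120758 0.3716444 2.1908602
#> 3 SRKW F 10 1.229521 0.5077780 0.2103787
#> 4 SRKW M 12 3.097747 0.4608733 3.0094044
```

NRKW females capture the most prey per hour and SRKW females the least —
NRKW females capture ~55% more per hour than NRKW males, while SRKW males
capture ~152% more than SRKW females. Calf presence suppresses capture by
adult females:

```r
af <- demography_table(d, "adult_females")
spec <- model_spec("n_capture_dives", "poisson", c("population", "calf"),
                   random = "week_year", offset = "log(duration_h)")
fit_glmm(spec, af, engine = "glmmTMB", REML = TRUE)
#> forage_fit [poisson, glmmTMB]: n_capture_dives ~ population + calf + ...
#>   n = 15, logLik = -34.54, AIC = 77.09
#>             term estimate     se statistic         p
#> 1    (Intercept)    2.500 0.6059     4.126 3.692e-05
#> 2 populationSRKW   -2.184 0.7090    -3.081 2.063e-03
#> 3        calfyes   -1.945 0.7173    -2.712 6.691e-03
```

Adult SRKW females make e^(−2.18) ≈ 0.11 times the prey-capture dives of
NRKW females per hour, and females with a calf ≤ 3 years make e^(−1.95) ≈
0.14 times the captures of females without, holding the rest fixed.

For processing raw sensor records and for the synthetic generator, see the
methods vignette (`vignettes/foraging-pipeline.Rmd`).

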