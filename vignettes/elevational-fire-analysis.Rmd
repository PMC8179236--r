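---
title: "Methods: the elevational distribution of forest fire and the climate velocity of VPD"
author: "fireElev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elevational fire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireElev)
```

## The statistical problem

In mountainous regions, moisture (persistent snowpack, late fuel drying)
historically suppressed fire at high elevation — a *mesic barrier*. As the
warm-season atmosphere dries, that barrier is expected to move upslope, and
with it the elevations at which forest burns. fireElev quantifies this with
three connected pieces of machinery:

1. **Where fire sits on the elevation axis.** For an ecoregion-year, join a
   DEM, a forest/woodland mask and a binary burn mask. With $B \in \{0,1\}$
   the burn state of a forest cell and $E$ its elevation, the quantity of
   interest is the *normalized* elevational burn distribution
   $$\frac{P(B\mid E)}{P(B)} \;=\; \frac{P(E\mid B)}{P(E)},$$
   the Bayes form on the right being robust to elevation-band choices: it is
   the density of burned-forest elevation divided by the density of forest
   elevation, renormalized to a probability density. **Z90** is its 90th
   percentile — the elevation below which 90% of the forest-fraction-weighted
   burn mass lies. **BA90** is the burned forest area above the (fixed) 90th
   percentile of *forest* elevation. Z90 asks "how high does fire reach,
   relative to where forest is"; BA90 asks "how much burns in the highest
   forest".

2. **How those metrics move in time.** A weighted quantile regression of
   burn elevation on year (check-loss minimization at $\tau = 0.9$) gives the
   Z90 trend; the slope times the number of fire years is the total change.
   Monotonic trends are tested with the Mann-Kendall statistic (classic, and
   with the Hamed-Rao autocorrelation correction). Fire-free years are
   excluded, as the metric is undefined there.

3. **Why they move.** Warm-season (May 1 - September 30) mean vapor pressure
   deficit (VPD) is the aridity covariate. The interannual regression of Z90
   (or BA90) on VPD, multiplied by the VPD trend over the record, yields the
   VPD-driven change; evaluating the regression at the trend-line VPD of the
   first and last year and integrating the forest hypsometry between the two
   predicted elevations yields the newly fire-exposed forest area. The
   elevational climate velocity of VPD,
   $$\frac{dE}{dt} \;=\; -\,\frac{\partial \mathrm{VPD}/\partial t}
   {\partial \mathrm{VPD}/\partial E},$$
   is the speed at which a VPD isoline moves uphill, an independent physical
   yardstick for the fire-elevation trend.

## The synthetic study

Real inputs (multi-decadal 30-m burn severity rasters, 10-m DEMs, daily
climate grids) are far beyond desk scale, so the package ships a seeded
generator whose ground truth is known, and every estimator is validated by
parameter recovery. The default study emulates 15 mountainous ecoregions
over 1984-2017.

**Landscape.** A 48 x 48 grid of 1-km cells; elevation is a linear ramp over
500-3500 m plus a smoothed Gaussian relief field (roughness 0.3 of a quarter
of the relief); forest is certain between 900 and 3200 m, tapering linearly
over 150 m — a coarse but serviceable montane forest band.

**Climate.** Warm-season mean VPD is generated directly (the daily path is
exercised separately through `vpdFromTRH()` and `warmSeasonMean()`):
$\mathrm{VPD} = 2.2 - 2\times 10^{-4} E + 1.78\times 10^{-3}(t - 1984)$ kPa,
plus a shared interannual deviation (sd 0.12 kPa) and a smoothed spatial
field (sd 0.05 kPa), clipped at zero. The lapse and trend make the true
elevational VPD velocity $1.78\times 10^{-3} / 2\times 10^{-4} = 8.9$ m/y —
about 300 m over the record — and the interannual sd matches the magnitude
of observed warm-season VPD variability.

**Fire.** Each year draws a Poisson(3) number of ignitions among forest
cells with probability proportional to the logistic flammability
$p = \mathrm{logit}^{-1}(\alpha + \beta\,\mathrm{VPD})$; each fire grows by
breadth-first region growing in which an offered 4-neighbour forest cell
joins with its own $p$; fires smaller than 4 cells (the 405-ha floor of
large-fire inventories, at 1-km cells) are discarded. Region growing rather
than independent per-cell burning keeps perimeters contiguous, which is what
makes Z90 variance realistic.

The flammability defaults ($\beta = 15$ per kPa, $\alpha = -25.2$) place the
system in a *barrier-controlled* regime: the join probability is near one at
the lower forest edge and falls through the site-percolation threshold near
2500 m, about 1.5 orders of magnitude over the forest span. This matters: a
logistic profile whose exponential tail spans the whole forest band is
shape-invariant under translation, so its normalized distribution — and
hence Z90 — would not respond to a VPD trend at all. Only when relative
flammability saturates below a moving transition does Z90 track the
barrier, which is precisely the mesic-barrier mechanism the analysis is
meant to detect. A consequence the user should know: annual burned fractions
are far higher than in real landscapes (percolation clusters are large), so
the generator emulates the *elevational structure* of burning, not absolute
burn rates, fire counts or fire-size distributions.

**Ground truth.** `trueZ90Oracle()` evaluates, per year, the expected
normalized distribution directly from the per-cell logistic probabilities
(no perimeter sampling) and takes its weighted 90th percentile; the true
velocity is trend/lapse in closed form. The recovery study (200 seeded runs
of 15 ecoregions x 34 years on 32 x 32 grids, 200 bootstrap replicates,
30-point-per-year subsamples) checks that the pipeline's median Z90 total
change and the VPD-attributed change agree in sign with the oracle, and that
the quantile-trend CI covers the oracle trend; those problem sizes are the
validation study's own design. Because the realized burn probability under
region growing is a monotone but nonlinear transform of the per-cell
logistic (growth compounds join probabilities), oracle and pipeline *levels*
can differ; the recovery criteria are therefore about signs and trend
coverage, not levels.

## Numerical and statistical choices

* **Elevation binning.** $\hat p(E)$ is an area-weighted histogram with
  50-m bins (configurable). The weight a burned cell contributes is
  cell area / $\hat p$(its bin), with the *piecewise-constant* bin value, so
  the weighted sample reproduces the binned burned/forest area ratio
  identically; a linearly interpolated density is available separately for
  plotting. The Bayes form makes results insensitive to the bin width, which
  the equivalence tests exercise.
* **Weighted quantile.** Frozen convention: weights are normalised to mean
  one, and the type-7 plotting position $h = (n-1)q + 1$ is located on the
  cumulative-weight scale with linear interpolation across value boundaries.
  With equal weights this is exactly `quantile(type = 7)`; with integer
  weights at central $q$ it matches the replicated-sample quantile; it is
  invariant to rescaling all weights (so cell-area units never matter). Its
  behaviour at extreme $q$ (near 0 or 1) follows the mean-normalised scale
  rather than the replicated sample — irrelevant at $\tau = 0.9$ with many
  cells.
* **Quantile regression.** The check loss is profiled over the slope: for a
  fixed slope the optimal intercept is the lower weighted $\tau$-quantile of
  residuals, and the profile is convex, so golden-section search (C++) finds
  the global minimum; a brute-force grid-search oracle verifies it. Each
  fire year's weights are normalised to sum one so years carry equal mass;
  years with more than `maxPointsPerYear` weighted points are subsampled
  proportionally to weight. On gridded data the optimum can be set-valued
  (flat); any minimiser is reported. The 95% CI is a seeded year-block
  bootstrap (resample years with replacement; 1000 replicates by default),
  chosen over rank inversion because burned cells within a year are strongly
  dependent; the percentile interval is widened, when necessary, to contain
  the point estimate. The reported p-value is the two-sided bootstrap sign
  probability of the slope. Fire-free years are excluded by default; because
  exclusion can itself induce apparent trends when such years cluster early
  in a record, `z90Trend()` offers a sensitivity mode that instead floors
  them at a chosen elevation (typically the minimum forest elevation).
* **Mann-Kendall.** Tie-corrected variance, continuity-corrected normal
  approximation. The Hamed-Rao variant detrends by the Sen slope, takes the
  rank autocorrelations, keeps lags significant at 5%, and rescales var(S)
  by the effective-sample-size factor (floored at 1 if the factor becomes
  non-positive). On short independent series the screening step makes
  Hamed-Rao slightly anticonservative — a known property, visible in the
  package's own calibration tests, where the classic variant holds the 5%
  level; Hamed-Rao earns its keep on autocorrelated series, where it removes
  most of the classic test's excess false positives.
* **Tercile composites.** Tercile membership by stable ordering (covariate,
  then year); middle third discarded. The Kolmogorov-Smirnov, two-sample
  Cramér-von Mises and Anderson-Darling statistics are computed on the two
  composites; p-values come from seeded permutation (9,999 replicates) —
  valid at any sample size and the only practical option at tercile sizes of
  ~11 years; KS switches to its asymptotic p above 25 per group.
* **Velocity.** Upslope-positive sign convention:
  $-\,(\partial\mathrm{VPD}/\partial t)\,/\,(\partial\mathrm{VPD}/\partial E)$,
  so rising VPD over the usual negative elevational gradient moves isolines
  uphill. Gradients below $10^{-5}$ kPa/m are flagged undefined rather than
  divided by. Ecoregion velocity defaults to the median of per-cell
  velocities (per-cell temporal trends over the ecoregion gradient); the
  mean is available.
* **Attribution.** Type I (OLS) regression is the default throughout,
  including the hypsometric exposure; type II (standardized major axis,
  slope $= \mathrm{sign}(r)\,s_y/s_x$) is provided for sensitivity analyses.
  Fire-free years are dropped for Z90 (undefined there, which biases the
  sensitivity toward zero — estimates are conservative) and kept as zeros
  for BA90. The percent change reported with an attributed change uses the
  regression-fitted metric value at the start-of-record trend-line VPD as
  its base; a non-positive base flags the percent undefined while the
  absolute change is kept. The total-change span convention is the record
  length in years (34 for 1984-2017); hypsometric endpoints use the
  trend-line values at the first and last calendar year.
* **Temperature decomposition.** Daily VPD uses the Magnus saturation curve
  (0.6108 exp(17.27 T/(T+237.3)) kPa) with actual vapour pressure pairing
  daily RH extremes with opposing temperature extremes. The frozen-RH series
  replaces RH by its calendar-day climatology smoothed with a +/- 7-day
  running mean (stabilises short records); the temperature share is the
  ratio of the frozen-RH trend to the observed trend, undefined when the
  observed trend is numerically zero.
* **Degenerate inputs.** Point-mass forest (single elevation) yields a
  single-bin density whose quantile is that elevation; constant trend
  responses return a flagged degenerate zero-slope result; empty burn years
  produce an explicitly flagged empty distribution that `zQuantile()`
  refuses with instructions to skip the year; overlapping elevation bands
  are rejected.

## File formats

Rasters travel as plain-text ESRI ASCII grids, burn perimeters as GeoJSON
(one MultiPolygon feature per year with a `year` property; rasterization by
even-odd ray casting of cell centres; an `area_ha` property supports the
405-ha floor), tables as CSV with `NA` for undefined, configurations as
YAML. Severity-coded burn rasters require an explicit class-mapping table
(code, retain) — encodings vary by data release, so the adapter never
guesses; unknown codes raise an error listing the observed classes.

## What passing tests do and do not show

The suite demonstrates (i) exact agreement of each estimator with
independent closed-form, hand-enumerated or brute-force oracles on toy
inputs; (ii) distributional identities (normalized density = binned ratio;
conservation of band areas; scale invariance); (iii) statistical calibration
(Mann-Kendall level, bootstrap reproducibility); and (iv) end-to-end
parameter recovery on the synthetic study. It does not show that the
generator's fire process matches real fire behaviour (it deliberately does
not: no fuels, wind, suppression, spread physics or daily progression), nor
that real severity products are handled beyond the format adapters, nor
anything about horizontal climate velocity or climatic water deficit, which
are out of scope.
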