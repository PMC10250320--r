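---
title: "Methods: detecting tree-cover change across biome boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting tree-cover change across biome boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

At its southern margin the boreal forest grades into temperate forest and
parkland; at its northern margin it thins into tundra. Two decades of
satellite-derived percent tree cover (annual continuous-fields products at a
few hundred metres resolution) are enough to ask whether the biome's edges
are moving: is cover being lost near the southern boundary while the
northern interior densifies? `borealtrends` packages the full analysis
chain for that question — robust per-series trend estimation, a spatially
informed transect sampling design, a boundary-relative coordinate that makes
transects comparable, disturbance and vegetation stratification, descriptive
profiles, and semiparametric profile models — together with a seeded
synthetic-landscape generator that serves as the test bed for every stage.

## Per-series trend estimation

Each plot contributes one annual series of mean tree cover. Its trend is the
Theil–Sen slope, the median of all pairwise slopes
$(v_j - v_i)/(t_j - t_i)$: robust to outliers (a fire year, a sensor
artefact) and assumption-light. Significance is assessed with the
Mann–Kendall score $S = \sum_{i<j} \operatorname{sign}(v_j - v_i)$, its
tie-corrected variance, the $\pm 1$ continuity correction and a two-sided
normal p-value — though, as is standard for mapping change, all trend
values are retained regardless of significance.

Interannual cover estimates are serially correlated, which inflates the
Mann–Kendall false-positive rate. `estimate_trend()` therefore applies
trend-free pre-whitening: estimate the slope $b$, detrend, estimate the
lag-1 autocorrelation $r_1$ of the residuals, remove it
($y''_t = y'_t - r_1 y'_{t-1}$), and add the trend back before
re-estimating. Two choices the method's literature leaves open:

* **Application threshold.** Pre-whitening is applied only when
  $|r_1| > 0.05$. Below that the correction is noise and needlessly costs
  one observation; the cut-off mirrors common implementations.
* **Missing years.** A 20-year window must have at least 15 usable years
  (`min_years = 15`, hard floor 4); sparser series return a
  flagged-missing estimate. With internal gaps the Sen slope and
  Mann–Kendall test use true year spacing, while the AR(1) step operates on
  the detrended residuals in observation order; series with unequal
  spacing cannot be pre-whitened and raise an error.

Relative change divides the absolute slope by the window-mean cover. Ratios
against near-zero means are unstable, so means below 1% cover (including
the negative means of temperature series, which reuse the same estimator)
yield a flagged `NA` rather than a number.

## Spatial structure and transect spacing

Placing transects closer together than the correlation length of the trend
field buys no information. The spacing is therefore derived from data: a
seeded uniform sample of pixels (10,000 by default), per-pixel trends, an
empirical semivariogram over great-circle distances, and a weighted
least-squares fit (weights = pair counts, via Levenberg–Marquardt) of an
exponential model $\gamma(h) = c_0 + c\,(1 - e^{-h/a})$. The *practical
range* — the lag at which the model reaches 95% of its sill, $3a$ for the
exponential — becomes the minimum transect spacing. Exponential, Gaussian
and spherical residual-correlation candidates (plus the independence null)
are also compared as intercept-only GLS fits by small-sample-corrected AIC;
the winning family is reported and reused in the profile models.

Numerical choices:

* **Lag binning** defaults to 25 km bins. The standalone variogram runs to
  500 km, but the *pipeline* fits only to 200 km: at longer lags the
  semivariance keeps climbing because of the deterministic south–north
  trend profile (a non-stationarity), and an unrestricted fit chases that
  drift into ranges of thousands of kilometres. Spacing is a short-range
  redundancy question, so short lags are the relevant ones.
* **Identifiability.** A fitted range counts only when the partial sill is
  at least 5% of the total sill *and* the practical range lies within
  twice the observed lag span — otherwise the variances never level off in
  the data and the fit is flagged, falling back to the configured spacing
  (133 km by default).
* **Correlation-structure selection** subsamples to 400 points: GLS with a
  spatial correlation is $O(n^3)$, and 400 points discriminate the
  candidate families reliably at these ranges.
* Distances are haversine great-circle distances in km; residual-model
  coordinates use an equirectangular km projection, adequate at regional
  extents.

## Sampling design and the boundary-relative coordinate

Transects are random south–north lines: longitudes drawn uniformly over the
shared extent of the two boundary polylines, snapped to the 0.05° plot
lattice, and accepted greedily while all pairwise spacings (evaluated at the
mid-domain latitude) stay above the minimum. Each transect is a contiguous
stack of 0.05° × 0.05° plots covering the span between its two boundary
crossings plus 20 plots (~110 km) beyond each boundary.

Latitude is a poor common coordinate when a biome's boundaries wander, so
plots carry a *standardized boundary distance* (SBD): the plot containing
the southern crossing is $-1$, the northern crossing $+1$, interior plots
interpolate linearly by index, and extension plots step outward by 0.025
per plot so the 20th reaches exactly $\pm 1.5$ (values are capped there).
Index-linear interpolation (rather than distance-linear) follows from
defining the coordinate "by the total number of plots"; with a fixed
lattice the two coincide.

Plot aggregation applies two rules: pixels of non-natural or unvegetated
classes (water, urban, cropland, wetland, bare, snow/ice) are dropped from
the plot mean, and a plot whose *modal* class is one of those is excluded
outright. The modal-class reading resolves an ambiguity (largest single
class, not the union of excluded classes) and matches how a dominant-class
map is normally used. Disturbance classification computes the fractions of
the footprint burnt and harvested since 1985; any sign of disturbance
classifies the plot, the larger fraction decides the type (ties go to
fire, deterministically), the year of that type's largest-area event is
recorded, and type × period gives one of five exhaustive categories.

## Profiles, strata and range shrinkage

Descriptive outputs are binned means along SBD (0.025-wide half-open bins,
120 over $[-1.5, 1.5]$), stratified means ± sample SD (denominator
$n - 1$) by disturbance category, vegetation class and latitudinal zone,
and a block-mean coarse trend map. Zones are configurable SBD intervals
with defaults: southern boundary $(-1.1, -0.9]$, interior $(-0.5, 0.5]$,
northern interior $(0.5, 0.9]$.

"Range shrinkage" quantifies the contraction of the latitudinal span of
treed area between two epochs (defaults 2000–2004 vs 2015–2019): plots
whose epoch-mean cover reaches 10% count as treed, the occupied span is the
distance between the 5th and 95th SBD quantiles of treed plots, and
shrinkage is the first-epoch span minus the second. The threshold and
quantiles are package choices (with sensitivity support via arguments);
because the quantiles are taken over the pooled treed distribution, a pure
southern loss also nudges the northern quantile slightly — the per-edge
shifts are reported alongside the net shrinkage for that reason.

## Smooth profile models

The relationship between trend and a predictor (SBD, mean cover, elevation,
climate means or climate trends) is modelled as a penalized cubic spline
(basis dimension 10, cross-validated down when strata are small) with the
stratum as an interaction: one smooth per disturbance category, or per
disturbance × vegetation combination. Transects enter as random
intercepts, and residuals carry an exponential spatial correlation (with
nugget) within transects, initialized at the variogram's practical range
and profiled by REML. Fitting uses `mgcv::gamm`, i.e. the mixed-model
representation of penalized splines with `nlme` estimating the correlation.
Because the explanatory variables are strongly collinear (a correlation
screen is provided), one model is fitted per predictor rather than one
joint model. Strata under 10 complete cases are dropped with a warning; a
constant predictor returns a flagged degenerate fit; if the mixed fit fails
to converge the model is refitted without correlation and the downgrade is
warned about. Validation is automated residual diagnostics (residual
moments, a normality test when sample size permits, fitted-observed
correlation) stored with the fit.

## The synthetic landscape

The generator emulates the statistical structure of the real inputs well
enough to exercise every pipeline stage with known truth:

* two sinusoidal boundary polylines; per-pixel true SBD;
* baseline cover as a piecewise-linear profile of SBD (low in the southern
  extension, ~50–55% in the interior, declining to a few percent in the
  tundra);
* a true trend profile $g(\mathrm{sbd})$ through control points
  $(-1.25, 0)$, $(-1, -0.13)$, $(0.5, +0.22)$, $(1, +0.05)$,
  $(\pm 1.25$–$1.5, 0)$ %/yr — southern losses, northern-interior gains —
  interpolated by a natural cubic spline;
* a spatially correlated *trend perturbation* field (exponential
  covariance, SD 0.08 %/yr, practical range 133 km). This is what gives
  the trend field detectable spatial autocorrelation; a static cover field
  alone would leave pixel trends spatially independent and the variogram
  stage vacuous;
* static spatially correlated cover heterogeneity (SD 4%, range 133 km)
  and per-pixel AR(1) interannual noise (SD 2%, $\rho = 0.3$). Both noise
  fields are damped by the binomial-shape factor
  $\sqrt{p(100-p)}/50$ (floor 0.15) of the expected cover — fractional
  cover is least noisy near its bounds — which keeps clipped values below
  1% under the defaults;
* Poisson disturbance patches (circular, radii 0.05–0.2°, ~2.2 per square
  degree, 70% fire) with years 1985–2019, an immediate drop (25% fire,
  35% harvest, capped at the local baseline cover — a site cannot lose
  more cover than it carries) and linear recovery that slows toward the
  south (2.5 %/yr at SBD 0, gradient 1.0 per SBD unit, floor 0.5);
* coarse 0.25° annual climate series with a 0.04 °C/yr warming ramp and a
  small precipitation trend; a correlated elevation field; a categorical
  land-cover grid with SBD-banded class probabilities plus water-body
  patches, so both plot exclusion and vegetation stratification are
  exercised.

Fields are simulated by circulant embedding (FFT), clamping the rare small
negative embedding eigenvalues to zero. Identical configuration and seed
reproduce byte-identical bundles, and every bundle carries a ground-truth
ledger (per-pixel true trend, $g$, SBD, the patch table, true climate
rates) sufficient to score any estimate.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: sensor saturation and view-angle artefacts,
land-cover misclassification, realistic fire-spread geometry, permafrost
and hydrological constraints, and disturbance regimes whose intensity
co-varies with climate. Results on the synthetic landscape validate the
*machinery*, not any ecological claim.

## Problem sizes used by the test suite

The default generator grid is 0.01° over a 10° × 15° domain, a desk-scale
stand-in for 250-m continental rasters. The test suite and the acceptance
script run the same domain at 0.025° (and smaller slices for unit tests),
which preserves all per-pixel statistical properties while keeping a full
pipeline run in seconds; Monte-Carlo checks use 20 pipeline replicates,
2,000 replicates for trend-recovery, 5,000 for test calibration, 20
variogram replicates at 2,000 points, and 50 smooth-model replicates at
320 points. End-to-end sign recovery is asserted on the undisturbed
stratum, since $g$ is by construction the undisturbed signal and disturbed
plots (notably 1985–1999 burns in strong recovery) legitimately pull zonal
means of the full sample.

## Known limitations

* The grid container is deliberately minimal (regular geographic grids,
  ASCII-grid text I/O); reprojection and sub-pixel area weighting are out
  of scope, and area fractions are pixel-count fractions.
* The shrinkage metric is a package-defined operationalization; threshold
  and quantile choices shift its absolute value (its sign is robust in the
  scenarios tested).
* With convoluted boundaries a transect uses the interpolated boundary
  latitude at its longitude — equivalent to the southernmost crossing of
  the southern line and the northernmost of the northern line for the
  shapes generated here.
* The variogram-based spacing inherits the usual fragility of variogram
  range estimation under low signal-to-nugget ratios; the fallback spacing
  keeps the pipeline usable when the range is not identifiable.
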