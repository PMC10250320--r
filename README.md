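# borealtrends

Tools for detecting and summarising directional change in satellite-derived
tree cover across the boreal biome — for remote-sensing ecologists and
biogeographers asking whether a biome's edges are on the move: cover loss
near the southern (temperate) boundary, densification in the northern
interior, and everything needed to measure it reproducibly.

## What it does

The analysis chain, each stage usable on its own:

1. **Robust trends per series.** Theil–Sen slope
   (median of all pairwise slopes $(v_j - v_i)/(t_j - t_i)$) with the
   Mann–Kendall test ($S$, tie-corrected variance, continuity-corrected
   $Z$) and trend-free pre-whitening: detrend, estimate the residual lag-1
   autocorrelation $r_1$, remove it ($y''_t = y'_t - r_1 y'_{t-1}$) and
   re-trend before the final estimate. Absolute change (% cover/yr) and
   relative change (slope / window-mean cover, guarded near zero cover).
2. **Spatial structure.** Empirical semivariogram
   $\gamma(h) = \frac{1}{2N_h}\sum (z_i - z_j)^2$ over great-circle lags,
   weighted least-squares fits of exponential / Gaussian / spherical
   models, the 95%-of-sill practical range, and information-criterion
   selection of a residual correlation family.
3. **Sampling design.** Random south–north transects with a minimum
   spacing taken from the fitted range; contiguous 0.05° plots spanning
   the biome boundaries with 20-plot extensions; a standardized boundary
   distance (SBD) mapping the southern boundary to −1, the northern to +1
   and extensions to ±1.5; land-cover exclusion rules, vegetation classes
   and five disturbance categories (fire/harvest × 2000–2019/1985–1999,
   plus undisturbed).
4. **Summaries and models.** Binned SBD profiles, stratified means ± SD,
   coarse trend maps, a range-shrinkage metric of the treed SBD span, and
   penalized-spline profile models with stratum interactions, transect
   random intercepts and exponential residual spatial correlation
   (`mgcv::gamm`).
5. **Synthetic landscape.** A seeded generator with known ground truth
   (trend profile, SBD, disturbance ledger) that exercises the full
   pipeline end to end.

## Worked example

```r
library(borealtrends)

# a 10 x 15 degree synthetic biome with known trend profile
run <- run_pipeline(pipeline_config(
  landscape = landscape_config(res = 0.025),
  seed = 5, spacing = "explicit", stages = "summaries"))
print(run)
#> <bt_run>
#>   [landscape] simulated with seed 13276860
#>   [variogram] skipped; explicit spacing 133 km
#>   [transects] 4 transects, 799 plots, spacing 133.0 km
#>   [plots] 778 retained, 21 excluded; disturbance: fire_1985_1999=30, fire_2000_2019=45, harvest_1985_1999=11, harvest_2000_2019=24, undisturbed=689
#>   [trends] 778 plot trends estimated
#>   [summaries] profile bins 116/120; shrinkage 0.0245

run$strata$zone
#>       zone        mean        sd   n
#> 1 interior  0.07243237 0.2037962 311
#> 2    north  0.19508088 0.1791820 125
#> 3    south -0.07569472 0.1745880  45
```

The southern-boundary zone loses ~0.08% cover per year while the northern
interior gains ~0.20% per year — the pipeline has recovered the asymmetry
that the generator imposed (true profile: −0.13 at the southern boundary,
+0.22 in the northern interior; zonal means also carry disturbance
effects and field noise). `run$profile` holds the 0.025-wide binned
SBD profile, `run$strata` the disturbance/vegetation/zone summaries and
`run$shrinkage` the change in the treed SBD span between 2000–2004 and
2015–2019.

Per-series use is just as direct:

```r
sen_slope(c(1, 3, 2, 5), 0:3)        # 1.166667 (= 7/6)
mann_kendall(c(1, 3, 2, 5))$S        # 4
estimate_trend(cover_values, 2000:2019)  # pre-whitened slope + test
```

## Layout

- `R/` — implementation (trend statistics, variograms, sampling design,
  aggregation, summaries, smooth models, landscape generator, pipeline).
- `inst/cli/boreal-trends.R` — command-line wrapper
  (`simulate`, `sample`, `variogram`, `trend`, `summarize`, `fit`,
  `run-all`).
- `vignettes/boreal-trend-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter choices, generator design, limitations.
- `tests/testthat/` — unit, property and end-to-end statistical tests.
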