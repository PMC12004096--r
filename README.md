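# pyroregions

Delineation of fire-regime regions from month-coded burned-area rasters.

Savannas and other fire-prone open ecosystems burn in characteristic
patterns — fire regimes — that vary across a biome: some areas sustain
large, frequent, numerous fires, others small and rare ones, and some burn
months later than their neighbours. `pyroregions` characterizes fire
regimes on a regular grid of square cells from annual burned-area rasters
in which each burned pixel carries its mapping month (1–12, 0 = unburned),
and partitions the grid into spatially contiguous *fire-regime regions*.

The pipeline:

1. **Fire events.** Burned pixels are merged into events by spatio-temporal
   contiguity: raster adjacency (8- or 4-connectivity, including the same
   location across years) with a gap of at most one month on the continuous
   month index `t = 12·(year − year₀) + month − 1`, plus a border-to-border
   proximity rule (150 m default) between temporally compatible components,
   iterated to a fixed point; events below 3 ha are then discarded.
2. **Regime metrics.** Six variables per cell and multi-year period: number
   of fires and burned area (both normalized to flammable area), the 50th
   and 99th smoothed-ECDF quantiles of event size, fire frequency (99th
   sECDF quantile of per-pixel years-burned counts), and the fire-season
   peak — the sECDF median of monthly burned area on a *fire-year* frame
   centred at the cell's modal burning month, a circular quantity. Cells
   with no fires are imputed (minimum fire size, frequency/count 1,
   neighbourhood season peak).
3. **Regions.** The variables are `ln(x+1)`-transformed, standardized, and
   ordinated by correlation-matrix PCA (axes retained to 95% variance,
   signs anchored so PC1 is a fire-activity gradient); the retained scores
   are clustered by Ward's minimum-variance criterion under a
   queen-contiguity constraint — only spatially adjacent clusters may merge
   — and the number of regions is chosen by a spherical-Gaussian mixture
   BIC evaluated on dendrogram cuts, with Dunn and silhouette indices for
   consultation.
4. **Drivers.** Random-forest classification accuracy (out-of-bag, with
   Clopper–Pearson 95% CI), covariate PCAs, redundancy analysis with an
   Ezekiel-adjusted R² and a permutation test, and signed correlations
   between the fire-activity gradient and anthropic / climatic gradients.
   Climate covariates include the dry season (months with mean PET above
   precipitation) and the peak of the dry season via the zero-capped
   climatological water-deficit recursion `CWDₘ = min(0, CWDₘ₋₁ + Pₘ −
   PETₘ)` restarted at the wettest month.
5. **Change.** Per-cell OLS trends `x = α + βt` with 80% confidence
   intervals classifying increase/decrease/none, and projection of later
   periods onto the first period's PCA space for cross-period comparison of
   activity.

A synthetic-landscape simulator plants recoverable regimes (contiguous
regions with Poisson event counts, lognormal sizes, wrapped-normal fire
seasons, fuel-recovery reburn dynamics), plus matching climate and
anthropic covariates, so the entire pipeline is testable without external
data.

## Worked example

```r
library(pyroregions)

grid    <- build_domain(10, 10, 50, 30)   # 10 x 10 cells of 50 x 50 px at 30 m
regions <- default_regions(grid)          # 4 planted regimes (high / intermediate / low / late-season)
cube    <- simulate_burned_cube(grid, regions, years = 9, seed = 2)
cube
#> burned_cube: 500 x 500 px, 9 years from 1985; 186032 burned pixel-years

events <- label_events(cube, connectivity = 8, buffer_m = 150, min_area_ha = 3)
events
#> fire_events: 1361 events (>= 3 ha) from 186032 burned pixel records; buffer 150 m, 8-connectivity

regimes <- regime_table(cube, events)
round(head(regimes[, 1:7], 3), 3)
#>   cell_id n_fires size_q50_ha size_q99_ha burned_area_norm frequency_q99 season_peak_month
#> 1       1 622.222       4.995        8.46            0.275         2.143             8.360
#> 2       2 666.667       4.860       21.24            0.322         2.250             8.173
#> 3       3 933.333       5.310        9.72            0.437         2.500             7.795

solution <- cluster_regions(regimes, grid)
solution
#> cluster_solution: k = 4 (BIC-selected from 15 candidates)
#>   k      bic        W       dunn silhouette degenerate
#> 4 4 807.9044 82.11984 0.25579513  0.5411829      FALSE
#> 5 5 812.2047 74.27380 0.08626795  0.4752665      FALSE
#> ...

adjusted_rand_index(solution$labels, cube$truth$labels)
#> [1] 1
round(tapply(solution$pca$scores[, 1], cube$truth$labels, mean), 2)
#>     1     2     3     4
#>  2.83 -0.46 -2.51  0.14
```

Read: a cell's `n_fires` of 622 means 622 events per 100 km² of flammable
area over the 9-year period; `burned_area_norm` 0.275 means 27.5% of the
cell's flammable area burned (cumulatively); `frequency_q99` 2.14 means the
most fire-exposed 1% of its pixels burned about twice; the season peaks in
mid-August. The BIC minimum at k = 4 recovers the four planted regions
exactly (adjusted Rand index 1), and the cluster means along PC1 order the
regions by fire activity: low (−2.51) < intermediate (−0.46) < late-season
(0.14) < high (2.83), matching the planted event-rate ordering. On other
seeds the selector may report five or six regions when a contiguous anomaly
(a patch of merged event complexes, or a run of fire-poor cells) is genuine
enough to stand out; the partition at the planted count remains essentially
exact.

Multi-period runs, environmental association and trend analysis are wrapped
by `run_pipeline()` (see `?run_pipeline`, and
`inst/scripts/run_pipeline.R` for a shell entry point); the methods are
documented in the vignette `vignettes/fire-regime-regions.Rmd`.

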