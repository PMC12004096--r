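---
title: "Delineating fire-regime regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating fire-regime regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroregions)
```

## The problem

Fire-prone open ecosystems — tropical savannas above all — do not burn
uniformly: different parts of a biome sustain characteristic combinations of
fire size, number, frequency, extent and timing, called fire regimes.
`pyroregions` characterizes fire regimes on a regular grid of square cells
from month-coded annual burned-area rasters (each burned pixel labelled with
its mapping month, 1–12), and delineates spatially contiguous *fire-regime
regions*: connected groups of cells with similar regimes. The pipeline has
five stages: fire-event delineation, per-cell regime metrics, ordination,
spatially constrained clustering with model selection, and downstream
analyses relating the regions to climatic and anthropic covariates and to
change over time. A synthetic-landscape generator with planted regimes makes
every stage testable end to end without any external data.

## Fire events from month-coded rasters

A *fire event* (fire polygon) is a maximal set of burned pixels connected
under two rules, applied as a transitive closure:

* **pixel adjacency** — two burned pixel records belong together if they are
  raster-adjacent (8-connectivity by default, 4 available; the same pixel
  location in different years also counts) *and* at most one month apart on
  the continuous month index `t = 12 (year - year0) + month - 1`, so a
  December fire continues into January across the calendar boundary;
* **proximity merging** — components whose pixel-dissolved borders lie
  within a buffer (150 m by default) of each other, and whose month spans
  overlap or are consecutive, are merged; merging is iterated to a fixed
  point. Distances are exact Euclidean distances between closed pixel
  squares, so edge-sharing pixels are at distance zero.

The rationale for the buffer is observational: satellite burned-area mapping
at a 16-day revisit misses pixels inside a burn and splits single fires into
fragments, inflating the count of small fires relative to the heavy-tailed
size distribution fire ecology expects. Merging across small gaps and
consecutive months reassembles those fragments. Whether the distance merge
should also require temporal compatibility is not observable from the data
dialect itself; the package requires it by default and exposes
`buffer_ignores_time` to drop the requirement.

Events smaller than a minimum area (3 ha by default, i.e. 34 Landsat pixels)
are discarded *after* all merging. The implementation reduces the fixed
point to a component graph problem: proximity edges between the
pixel-adjacency components are found once at pixel level (touching pairs by
an offset join; gap pairs by a block join over boundary pixels, where the
minimum between non-touching sets is always attained), after which only the
time-compatibility fixpoint iterates. The test suite checks the result
against a brute-force union-find over the literal pairwise relation on
random cubes.

## The six regime variables

For each cell and multi-year period (9 years in the reference design):

1. **number of fires** — events intersecting the cell, normalized to
   flammable area (reported per 100 km² of flammable area; the constant is
   an argument);
2. **median fire size** and 3. **99th-percentile fire size** — sECDF
   quantiles of the sizes of intersecting events, each taken with its full
   area rather than the within-cell clip (events were deliberately made
   small relative to cells by the grid design, so whole-event attribution is
   the intended semantic; a clipped variant would be a one-line change in
   `compute_regime()`);
4. **burned area** — summed burned pixel area over the period (within-cell
   pixels only), divided by flammable area; reburning can push it above 1;
5. **fire frequency** — the 99th sECDF quantile of the per-pixel counts of
   years burned (0–9, zeros included for never-burned pixels);
6. **season peak** — the sECDF median of monthly burned area on the
   *fire-year* frame, mapped back to a fractional calendar month.

The fire-year places each cell's modal burning month at position 6 of 0–11,
so that seasonality is comparable between cells whose fire seasons peak at
different calendar times; ties take the earliest month. The season peak is a
circular quantity: all averaging of months (including the no-fire
imputation below) uses circular means, and the statistic is equivariant
under calendar rotation.

### The sECDF smoother

A smoothed ECDF is interpolated linearly between the *distinct observed
values*, each placed at the midpoint of its cumulative-probability step. For
an all-distinct sample this is exactly interpolation at the plotting
positions `(i - 0.5)/n` (`quantile(..., type = 5)` in base R, used as the
oracle in tests). The distinction matters for tied data: per-pixel
years-burned counts are small integers, and a rank-position smoother would
return only integers, making the frequency variable jump discontinuously
between plateaus as a cell's burn probability crosses a threshold. The
distinct-value smoother responds continuously to the composition of the
counts, which is both the natural reading of "smoothing" a discrete ECDF
and materially better behaved downstream.

### Cells with no fires

Clustering needs a complete table, so cells with no events in a period are
imputed: both size quantiles and the raw burned area are set to the minimum
fire size (3 ha, then normalized), frequency and the fire count to 1 (the
count normalized like real counts), and the season peak to the circular
mean of the eight neighbouring cells' peaks, expanding ring by ring (with a
message) if the whole neighbourhood is undefined. Imputed rows are flagged.

## Climate covariates

Per cell and period, from monthly temperature, precipitation and potential
evapotranspiration (PET): the pooled-month mean temperature; the dry-season
set (months whose mean PET strictly exceeds mean precipitation, computed
once per cell-period); dry-season temperature and precipitation; the mean
annual precipitation total; and the peak of the dry season, defined through
the climatological water deficit

\[ \mathrm{CWD}_m = \min(0,\ \mathrm{CWD}_{m-1} + P_m - \mathrm{PET}_m), \]

a running, zero-capped water balance restarted (from 0) every 12-month
cycle beginning at the period-mean wettest month (ties earliest). Leading
months before the first cycle and trailing incomplete cycles are dropped —
partial cycles would bias the minima. The peak dry season is the calendar
month of the most negative mean CWD. The recursion depends on `P - PET`
only, so it is invariant to adding a constant to both series (a property
test). Gridded climate fields are averaged to cells with exact area
weights (`zonal_mean()`), computable in closed form for axis-aligned
rasters and grids.

## Ordination and spatially constrained clustering

The five activity variables are `ln(x + 1)`-transformed (seeking normality;
the season peak stays on the month scale) and standardized; a PCA on the
correlation matrix follows. Axes are retained up to 95% cumulative
variance, and axis signs are anchored (burned area positive on PC1, season
peak positive on PC2) so that PC1 is reproducibly a *fire-activity
gradient* and scores are comparable across runs and periods.

Regions are delineated by agglomerative Ward (minimum-variance) clustering
in which only clusters adjacent in the queen-contiguity graph may merge;
adjacency lists union on merge and dissimilarities update by the
Lance–Williams recurrence on squared Euclidean distances, with ties broken
by the smallest pair of member ids. On a complete graph the merge sequence
reproduces `stats::hclust(..., "ward.D")` exactly (an acceptance check).
Disconnected graphs cluster per component and components never merge, so
geographically disconnected areas with similar regimes become different
regions by construction. Every dendrogram cut therefore yields spatially
connected clusters.

### Choosing the number of regions

Each candidate `k` cuts the dendrogram and is scored by BIC under a
spherical Gaussian model, with the Dunn index and mean silhouette width
attached for consultation. Two scoring variants exist, and the choice is a
substantive one. The plug-in ("hard") form
\(n d \ln(W_k/(nd)) + \ln(n)\,k\,d\) evaluates the hard partition's
within-cluster sum of squares \(W_k\); because Ward-optimized cuts remove a
roughly scale-free 10–20% of \(W\) per extra cluster even from pure noise,
the likelihood term falls by far more than the \(\ln(n)\,d\) penalty at
moderate `n`, and the score decreases almost monotonically in `k` — it
cannot select a small `k` regardless of the data. The default ("mixture")
form evaluates the same cut as a spherical Gaussian *mixture* (cluster
means, shared variance \(W/(nd)\), mixing proportions equal to cluster
shares) with penalty \(\ln(n)(kd + k)\): splitting a genuinely Gaussian
cluster into two half-clusters leaves the mixture likelihood nearly
unchanged, so the criterion has an interior minimum at real structure. On
planted well-separated Gaussian blobs the mixture form recovers the true
`k`; the hard form is retained behind `bic = "hard"` for comparison.

A five-variable variant excluding the season peak (`drop_season = TRUE`)
reruns the identical path, to probe how much of a region's distinctiveness
is carried by seasonal timing alone.

## Environmental association and temporal change

The explanatory analyses treat the regions as a classification target and
the transformed fire variables as a multivariate response:

* **random forests** (500 trees, `sqrt(p)` predictors per split) classify
  region labels from a covariate set; the out-of-bag accuracy is reported
  with a Clopper–Pearson 95% binomial interval and permutation variable
  importances;
* **covariate PCAs** on the anthropic set (anthropic area %, its change,
  population and livestock densities, the two densities
  `ln(x + 1)`-transformed) and the climatic set, sign-anchored so PC1 means
  "more human presence" and "hotter dry season" respectively;
* **redundancy analysis** regresses the fire variables on a covariate
  matrix; \(R^2\) is the constrained variance fraction
  \(\mathrm{tr}(\hat Y^\top \hat Y)/\mathrm{tr}(Y_c^\top Y_c)\), adjusted by
  the Ezekiel correction \(1-(1-R^2)(n-1)/(n-m-1)\), and tested by
  permuting rows of the predictors with
  \(p = (1 + \#\{R^2_{perm} \ge R^2\})/(1 + n_{perm})\) — never exactly
  zero. Aliased predictors are dropped with a message. The hand-written
  \(R^2\) machinery is cross-checked against `vegan::rda()` in the tests;
* **gradient relations** report Pearson (with CI) and Spearman correlations
  between per-cell PC1 scores of the fire PCA and a covariate PCA, with a
  sign verdict only when the Pearson CI excludes zero.

Temporal change is quantified two ways. Per-cell OLS trends
\(x = \alpha + \beta t\) are fitted to annual series of the five annual
variables (and to period-level series for frequency and PC1), with the
predictor centred at the series start so \(\alpha\) is the starting level;
an 80% confidence interval from the t distribution with `n - 2` degrees of
freedom classifies each cell as increase (interval above zero), decrease
(below), or none. No multiple-testing correction is applied. The circular
season series is unwrapped around each cell's circular modal month before
fitting, so a drift across December–January does not masquerade as a jump.
Second, later periods are projected onto the first period's PCA space —
the reference center, scale and loadings, no refitting — so per-cell
activity scores are directly comparable across periods; projecting the
first period reproduces its scores exactly, and per-cell differences plus a
region-transition table summarize the change.

## The synthetic landscape

`simulate_burned_cube()` plants a known regime structure: contiguous
regions, each with an event rate (Poisson per region-year), a lognormal
event-size distribution, a wrapped-normal seasonal month distribution
around a peak month, and a reburn propensity. Events grow as connected
pixel blobs by stochastic breadth-first dilation from a uniform seed pixel —
irregular shapes without fire-spread physics — and may span two consecutive
months. Fuel is tracked per pixel: a pixel burned within the last
`recovery_years` (2 by default, a wet season or two of regrowth) carries
fire again only with the reburn propensity, and fully recovers afterwards,
which keeps the simulated regimes stationary in time. Two design choices
deserve emphasis:

* **ghost padding.** Each region simulates on its own fuel bed dilated by
  half a cell in every direction, with seed counts scaled by the padded
  area and events cropped to the region's cells. Without it, cells at
  domain edges and regime boundaries receive systematically less incoming
  fire than interior cells, and the constrained clustering — correctly —
  reports those deficit bands as extra regions. With it, every cell sees
  the homogeneous event climate of its own regime.
* **regime defaults.** The default landscape is four quadrants of a 10×10
  grid of 1.5 km cells (50 × 50 pixels of 30 m), 9 years: high activity
  (3.2 events/cell/yr, 13 ha median), intermediate (1.8, 8 ha), low
  (1.5, 5 ha), and a late-season region of small but numerous fires
  (3.0, 5.5 ha) peaking in October against August elsewhere, with a tight
  season. Reburn propensities grade with activity (0.55/0.5/0.5/0.7) so
  the years-burned distributions spread in the active regimes. The low
  region sits diagonal to the high region so their contrast is not blurred
  by adjacency. The parameters were chosen for separability and per-cell
  estimator stability of the planted regimes — each cell sees enough
  events for stable quantiles — not for landscape realism.

`simulate_climate()` adds a latitudinal temperature gradient (north hotter),
sinusoidal precipitation whose phase can differ by region (so dry-season
timing contrasts are recoverable through the CWD machinery), near-constant
PET, and optionally a planted flammability gradient: regions with higher
event rates get hotter dry seasons and deeper precipitation troughs, so a
positive climate–fire relationship exists to recover.
`simulate_anthropic()` draws anthropic covariates whose means are ordered
inversely to regional event rates (a coupling strength argument allows a
null variant), plus a flammable fraction decreasing with anthropic area.

What the generator does *not* emulate: fire-spread physics, fuel and
vegetation heterogeneity inside a region, real geography, inter-annual
climate forcing of fire, and observational noise in the burned-area maps.
Passing tests therefore demonstrate that the pipeline recovers structure
faithfully from data whose generating process matches its assumptions; they
do not validate the mapping of any real landscape.

### What recovery tests can and cannot demand

With 100 cells, per-cell regime statistics are estimates from a few dozen
events, and two irreducible phenomena create genuine small-scale structure
inside planted regions: buffer-merged event complexes inflate the size
quantiles of the handful of cells they touch, and Poisson luck clusters
fire counts. A faithful model-selection criterion occasionally reports such
a contiguous anomaly as a fifth or sixth region — the analogous phenomenon
appears in real regionalizations as distinct sub-regions of large fires
inside larger regions. The package's recovery checks therefore treat exact
recovery of the planted cluster count as the demanding end of the spectrum,
and the companion properties (partition agreement at the planted count,
activity ordering, seasonal timing, gradient signs) as the robust core.

## Numerical choices and degenerate inputs

* Ties: modal months, wettest months and dry-season peaks take the earliest
  month; Ward merge ties take the smallest member-id pair.
* `W = 0` at a dendrogram cut is floored at machine epsilon and flagged.
* Constant variables abort the PCA with the column named.
* All-zero burned-area vectors make the fire-year, season peak and
  imputation-source values `NA`; the trend fitter drops missing years and
  requires three observations.
* A perfect OLS fit yields a zero-width interval and classifies by the sign
  of the slope.
* Empty event lists flow through as empty summaries, not errors, except
  where a contract requires data (e.g. `secdf_quantile` on an empty
  vector).
* Problem sizes: module tests run on 6×6-cell landscapes with 20-pixel
  cells and scaled-down rates; the recovery study runs the full default
  scale over 20 seeds; the event-delineation oracle runs on random cubes up
  to 50×50×24 months.

## Known limitations

* The regionalization is a single global cut of one dendrogram; nested or
  sub-regional structure is visible in the merge history but not explored.
* The RDA permutation test permutes rows freely, ignoring spatial
  autocorrelation, so its p-values are anti-conservative on smooth fields.
* Whole-event size attribution double-counts large events across the cells
  they intersect (by design, matching the grid-sizing rationale).
* Raster I/O is plain-text (ESRI ASCII grid); no projected CRS metadata is
  carried, and inputs are assumed to be in an equal-area Cartesian frame.
* The month index treats the mapping month as exact; sub-month timing and
  multi-month smouldering beyond two consecutive months are not modelled.
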