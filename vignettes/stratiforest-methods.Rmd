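---
title: "Pixel-based forest stratification: models, design choices and limits"
author: "stratiforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-based forest stratification: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Carbon-offset forest projects must report inventory estimates with verified
confidence bounds, and the field cruise that produces them is the single
largest recurring cost. When airborne laser scanning (ALS) and optical
imagery are available wall to wall, the landscape can be cut into small
pixels, a cheap training sample can parameterize models linking the imagery
to stand attributes, and the landscape can then be *stratified* on the model
predictions so that a second, targeted sample yields tighter property-level
bounds with fewer plots. stratiforest implements that two-phase workflow
end to end for a grid of 0.04 ha (20 m) cells, together with a synthetic
landscape generator that makes every stage testable without proprietary
flight or field data.

The pipeline (`run_pipeline()`) is: summarize layers to the grid →
reduce image feature blocks by PCA → screen predictors with the Lasso and
fit stand models → predict every cell and bin the volume proxy into strata
→ allocate and place the second-phase plots → cruise them → post-stratified
estimation.

## Models and estimators

**Stand models.** Basal area (BA, m²/ha) and stems per hectare (TPH) follow
a log-linear model \(\ln y = X\beta + \varepsilon\); conifer basal-area
share follows a logistic model on the proportion scale (quasi-binomial,
tally-count weights). Predictors are screened by the Lasso
(`glmnet::cv.glmnet`, 10-fold, seeded folds, pure-minimum rule — the
one-standard-error rule is deliberately off) and the selected set is
*refit by unpenalized least squares*, so reported coefficients are ordinary
least-squares estimates on the selected design. Back-transformation of log
models optionally applies the log-normal correction
\(\exp(\hat\sigma^2/2)\); a paired simulation in the test suite verifies the
correction reduces mean bias. A Pearson chi-square normality test of the
residuals is computed with every log fit.

Zero responses under the log transform use a configurable additive offset
(default +1, engaged only when zeros are present and removed after
back-transformation), so noiseless positive data are fit exactly.

**Volume proxy and stratification.** Each cell's proxy is
\(v = \widehat{BA} \times \bar h\), with \(\bar h\) the mean canopy-height-model
height of the cell. Forested cells are partitioned into `k` strata by an
*exact* minimum within-bin sum-of-squares binning of \(v\), solved by
Fisher's \(O(kn^2)\) dynamic program on the sorted unique values. Exactness
is the point: the DP is verified against full enumeration for every
\(n \le 14, k \le 4\), and by construction dominates equal-width and
equal-frequency binning at any \(k\). The stratum count `k` is a
configuration parameter (the field outcome it emulates used 35 forested
strata); an SSE-versus-k scan is available through repeated calls so users
can pick an elbow.

**Minimum stratum area.** Strata below 4.05 ha (10 acres) are dissolved
smallest-first: each cell of an undersized stratum moves to whichever
stratum *adjacent in proxy rank* is nearest in standardized attribute space
(z-scored Euclidean distance over BA, height, TPH and conifer share,
landscape-wide standard deviations). We interpret "edge" cells as
bin-boundary cells, i.e. adjacency in proxy rank, not spatial adjacency;
the spatial reading is a documented alternative that would require a
contiguity graph the method otherwise never needs. Labels are renumbered to
ascending proxy mean after every dissolution, so the stratum count never
increases and no cell ever jumps a rank.

**Sample allocation.** Neyman allocation sets
\(n_h \propto N_h S_h\) (or \(N_h S_h/\sqrt{c_h}\) with costs). The integer
allocation is obtained by greedy marginal variance reduction — provably
optimal for the separable convex objective \(\sum_h W_h^2 S_h^2 / n_h\) —
rather than by Hamilton rounding of the continuous quotas, because largest
remainder does not always attain the integer optimum the module's
brute-force invariant demands. Strata too thin to estimate \(S_h\) from
phase-1 plots use the model-based stand-in: the standard deviation of the
back-transformed per-cell predictions within the stratum
(`model_variance()`). A floor (default 2 plots) keeps every sampled
stratum's variance estimable; floors may push the realized total above the
request and are flagged.

**Estimation.** Plots expand by prism arithmetic: each tallied tree
represents exactly `BAF` m²/ha of basal area (so plot BA = BAF × count) and
`BAF / (π (DBH/200)²)` stems/ha. Post-stratified estimates use the classic
stratified estimators: mean \(\sum_h W_h \bar y_h\) with \(W_h\) the area
share, variance \(\sum_h W_h^2 s_h^2/n_h\), and a half-width from Student's
t with Satterthwaite degrees of freedom (a z option exists for
cross-checks). The "90% accuracy" statistic is the two-sided 90% half-width
as a percent of the mean — the definition is implied but never spelled out
in the tradition this follows, so it is fixed here and exposed. Strata with
fewer than two plots at estimation are folded into the nearest proxy-rank
stratum and logged. Strata-level tree lists average per-tree expansions by
species and 5 cm diameter class; basal area recomputed from a list equals
mean plot basal area exactly.

**Sample efficiency.** For an auxiliary variable with squared correlation
\(R^2\), `sample_efficiency()` returns \(2(1-\rho)\), \(\rho = \sqrt{R^2}\):
the fraction of correlated plots needed to match an uncorrelated sample's
precision. The published table this reproduces contains one internally
inconsistent row (printed 59.1% where \(2(1-\sqrt{0.493})\) = 59.6%,
presumably an unrounded \(R^2\) upstream); that row is excluded from the
acceptance checks and noted here.

**Grid-size selection.** `scan_sizes()` extracts every layer's mean and
standard deviation in circles of area equal to each candidate cell size
(\(r = \sqrt{a/\pi}\)) around the plots, runs an exhaustive best-subset
search under \(BIC = n\ln(RSS/n) + (k+1)\ln n\) per size (guarded at 10⁶
models), and selects the area with the lowest BIC (ties to the smaller
area). Both BIC and \(R^2\) are reported per size, since "variation
explained" plots may be drawn from either.

## The synthetic landscape: what it emulates, what it does not

The generator's defaults state the world the method was built for: a
~10 000 ha second/third-growth redwood–Douglas-fir–tanoak property gridded
to 0.04 ha cells, cruised with a 4.6 m²/ha BAF prism at a 14 cm DBH
threshold, with GPS plot location error of 10 m at the 95th percentile, and
raster deliverables at 0.5 m (CHM), 1 m (DEM) and 0.6 m (bands).

* **Latent fields.** BA and TPH are log-normal transforms of Gaussian
  random fields with exponential covariance (practical-range convention),
  sharing a common component (ρ ≈ 0.5); conifer share passes a third field
  through a logit link. Log-normal marginals match the published summary's
  skew (BA 0–116, mean 40.7; TPH with a long right tail). Marginal sd
  values are not published; ba_sd = 20 m²/ha and tph_sd = 1500/ha were
  chosen once to reproduce the printed ranges and not revisited. Fields are
  simulated by 2-D circulant embedding (FFT), so large grids stay cheap and
  a seed fixes every draw bit-for-bit.
* **Stems.** Cell stem counts are Poisson at the target density (capped so
  a cell cannot hold more ≥ 14 cm stems than its target BA allows);
  diameters are `min_dbh + gamma` with the mean solved per cell so
  E[DBH²] equals the target quadratic mean diameter — realized BA is
  therefore calibrated to the field, and the truth table is *recomputed
  from the realized stems*, making the aggregation-consistency invariant
  exact by construction. The stem floor defaults to the measurement
  threshold (14 cm): truth then aggregates exactly the measurable stand. An
  earlier draft generated 10 cm stems and prism estimates sat ~28% below
  "truth" — truth carried basal area no ≥ 14 cm cruise can see.
  Heights follow a two-class Chapman–Richards allometry (conifer asymptote
  65 m, hardwood 40 m) with log-normal noise; species is Bernoulli in the
  cell's conifer share; 5% of stems are standing dead.
* **Rasters.** The CHM is the upper envelope of per-tree paraboloid crown
  caps plus 15 cm vertical noise. Image band expectations are affine in
  canopy cover \(1-e^{-0.03\,BA}\) and conifer share of the containing
  cell — monotone in expectation by construction, exact when the noise is
  zero — with iid pixel noise as the only within-cell texture. The DEM is a
  smooth two-component sinusoid; slope and aspect are derived numerically
  by Horn's method (one code path serves synthetic and real DEMs alike).
  The crown deliverable is produced by running the package's own watershed
  on the simulated CHM, mirroring how a vendor produces it.
* **Not emulated.** Discrete-return point clouds, radiometric realism,
  LiDAR intensity (so intensity features are simply absent), multi-species
  allometry, and within-cell reflectance texture beyond noise. A green test
  therefore establishes the *procedure* (recovery, calibration, gain), not
  radiometric transferability to a particular sensor.

**GPS error** is circular bivariate normal with
\(\sigma = r_{95}/\sqrt{\chi^2_{2,0.95}} = r_{95}/2.4477\); a 10 000-draw
calibration check holds the realized 95% radius to ±1%. Plots are assigned
to the cell containing their *nominal* grid coordinate; jittered centres
that cross cells are a flagged, studied consequence, not an error.

## Numerical and procedural choices

* Cells are half-open squares \([x, x+s) \times (y-s, y]\), ids row-major
  from the NW corner; variances are within-cell population variances.
* Aspect is circular: per-cell statistics use unit vectors, so a cell of
  constant aspect has zero circular variance across the 0/360 wrap.
* Plane departure (topographic item with no published formula) is the RMS
  residual of cell DEM pixels from the bilinear surface through the four
  corner elevations.
* Watershed crowns: Gaussian smoothing (default σ = 0.5 m) steers seeds
  (8-neighbour local maxima ≥ 2 m) and flooding order; ties break toward
  the lower pixel id; crowns below 1 m² merge into the neighbour with the
  longest shared border. Labels are masked back to the *measured* surface
  at the height threshold, so smoothing cannot grow crowns past real
  canopy — this keeps crown closure an exact covered-area share and makes
  the closure mass-conservation invariant hold to round-off.
* Crown–image fusion takes the mean band value over crown pixels (not
  centroid sampling) — the unstated alternative is noted as such.
* PCA uses the correlation matrix (feature blocks mix units); a covariance
  mode exists for tests. Retention is fixed at k = 8 per set, with a
  Kaiser-criterion option behind a flag. Loading signs are fixed by making
  each vector's largest-magnitude element positive. "LI" components are
  computed from the CHM-derived feature block, the more defensible of the
  two readings of an ambiguous source.
* Reported \(R^2\): both transformed-scale (used for sample efficiency)
  and natural-scale values are kept, because which scale the published fit
  statistics used is unstated.
* Phase-1 and phase-2 plots are treated as separate phases and both enter
  estimation by post-stratification; floors are the rule (default 2), the
  realized 15-plot minimum of the emulated project being an outcome, not a
  rule.

## The grid-size recovery experiment

Recovery of a *generative* scale needs a landscape whose scale is known
exactly, so `simulate_scale_landscape()` states one: square blocks of side
36 m with independent standard-normal levels, an observation layer with
iid pixel noise (sd 1.5), and plots at interior block centres. For a plot
at a block centre, the expected \(R^2\) of the circle-mean predictor is
computable in closed form from the geometry: the covariance with the
response is the fraction of circle pixels in the home block, and the
circle-mean variance is the same-block pair fraction plus noise/m. That
oracle puts the optimum at the 0.10 ha candidate (≈ the inscribed circle,
\(\pi s^2/4\)); the acceptance test requires `scan_sizes()` to land within
one candidate step of the oracle optimum in ≥ 80% of 25 seeded replicates.
A Gaussian-field version of this experiment has a much flatter theoretical
\(R^2\) profile and would test luck more than procedure; the block world
was chosen for identifiability and is documented as such.

## Known limitations

* No GeoTIFF/true GeoJSON geometry stack: rasters travel as Esri ASCII
  grid text, crown geometries as convex-hull GeoJSON (metrics always come
  from exact pixel sets). Suitable for interchange, not for survey-grade
  polygon work.
* The \(O(kn^2)\) binning DP is exact but quadratic; for landscapes beyond
  ~10⁵ cells, pre-binning the proxy to a fine quantile grid is the
  intended route.
* Allometries (carbon, board-foot) are labelled stubs exercising the
  reporting slots; substitute regional species-specific equations for any
  real inventory.
* Edge effects: prism plots near the landscape boundary see truncated
  stands (no boundary-overlap correction), a small negative bias visible
  only in synthetic worlds with hard edges.
* Monte-Carlo design comparisons observe the sampled cell's true value,
  isolating the design effect from measurement error by construction.
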