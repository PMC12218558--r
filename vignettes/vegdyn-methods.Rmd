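---
title: "Methods: change points, trends, and driver attribution in NDVI records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: change points, trends, and driver attribution in NDVI records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegdyn)
```

`vegdyn` implements the analysis chain used to characterise multi-decade
vegetation dynamics over a watershed from a gridded NDVI record: seasonal
compositing, regional change-point detection, per-pixel trend and coverage
mapping, driver correlation, and spatial stratified-heterogeneity
attribution. This vignette is the package's account of the science behind
each stage: the models, their assumptions, the tunable parameters, the
numerical conventions, and what the synthetic test world does and does not
establish.

## 1. Compositing: from sub-monthly composites to a growing-season field

NDVI from optical sensors is biased *low* by residual cloud and aerosol
contamination, never high. The maximum value composite (`mvc()`) exploits
this asymmetry: the per-cell maximum over the sub-period images of a month
is the best available estimate of the surface signal. A cell is masked only
when every input is masked; a single clear composite suffices.

The annual growing-season field (`growing_season_ndvi()`) combines the
May–September monthly maxima in one of two modes, because "the average of
the maximum values over the season" genuinely admits two readings:

* `monthly_max_mean` (default): the mean of the five monthly maxima. This
  is the smoother statistic and the default because it uses all five months
  of information.
* `seasonal_max`: the single seasonal maximum, cell-wise always at least as
  large as the mean of maxima.

One mode must be used consistently within a run; the change-point and trend
results are mode-conditional, and the run manifest records the mode.

The regional series (`regional_mean()`, `regional_series()`) is the
unweighted mean over unmasked cells. An optional latitude-cosine weighting
exists for wide-latitude domains but is off by default: over a ~4°-latitude
watershed the cosine varies by under 3% and the unweighted mean is the
convention in this literature. A watershed mask raster may restrict the
mean; whether to use the strict basin mask or the bounding box is left as
an input, since published regional series rarely state it.

## 2. Ordered cluster analysis: the change point

Given the annual series \(x_1,\dots,x_n\), every admissible split \(\tau\)
is scored by the total within-segment sum of squared deviations
\[
S_n(\tau) = \sum_{t \le \tau}(x_t-\bar x_\tau)^2
          + \sum_{t>\tau}(x_t-\bar x_{n-\tau})^2 ,
\]
and the minimiser \(\tau^*\) is the change point. This is exactly the
two-segment least-squares (ordered clustering) criterion: it detects a
shift in the *mean regime*. Three numerical conventions matter:

* **Scan range.** \(2 \le \tau \le n-2\), so both segments always hold at
  least two points and the jump test is defined at the optimum. (A printed
  range of \(-1 \le \tau \le 1\) circulating for this method is an obvious
  typographical corruption; it would leave nothing to scan.)
* **Ties.** Exact ties at the minimum resolve to the earliest \(\tau\) and
  are recorded in the fit object (`tied_taus`).
* **Degeneracy.** A constant series makes \(S_n\) flat; the fit is flagged
  `no_change_point` rather than reporting an arbitrary split.

A multi-valley \(S_n\) curve is the classic signature of more than two
regimes, so interior local minima within 10% (the `prominence` default) of
the global minimum are reported as `secondary_minima` — purely diagnostic;
multi-change-point segmentation is out of scope.

**The jump test.** The literature this method comes from prints a test
value \(|T|\) against a critical value of 1.64 at \(\alpha = 0.05\) without
stating the statistic. `vegdyn` adopts the standard pooled two-sample t
statistic for a mean jump,
\[
|T| = \frac{|\bar x_\tau - \bar x_{n-\tau}|}{s_p\sqrt{1/\tau + 1/(n-\tau)}},
\]
with \(s_p\) the pooled within-segment standard deviation. The printed 1.64
equals the standard normal quantile at \(1-\alpha\) — a one-sided-quantile
convention despite the "\(\alpha/2\)" notation that sometimes accompanies
it. `critical_value()` reproduces the printed convention by default and
offers the strict two-sided quantile (1.96 at 0.05) behind `two_sided =
TRUE`; the discrepancy is a documented property of the source convention,
not of this implementation. Degenerate variances are handled explicitly:
zero pooled variance with unequal means gives \(|T| = \infty\)
(significant), with equal means \(|T| = 0\).

Note what the estimator can and cannot see: a *slope kink without a level
shift* produces no mean jump, and the \(S_n\) valley of a continuous
piecewise-linear series does not sit at the kink (for a shallow-decline /
steep-rise shape it lands several years late). A change point detected by
this method is a mean-regime shift, and the synthetic generator is built
accordingly (section 6).

## 3. Trends and classification maps

`pixel_slope()` is the closed-form OLS slope of value on the time index
\(i = 1..n\), vectorised over cells; a cell needs at least 3 valid years
(masked otherwise, counted in diagnostics). Trend significance is not
computed: the five-level classification below is defined on the raw slope.

**Trend classes.** The five levels use thresholds (in NDVI·yr⁻¹)
−0.0019, −0.0010, −0.0002, 0.0006. As printed in the source literature the
bins overlap at every interior endpoint; `classify_trend()` uses the unique
true partition consistent with the closed extreme bins:
obvious degradation \(\le\) −0.0019 < mild \(\le\) −0.0010 < stable
\(\le\) −0.0002 < slight < 0.0006 \(\le\) significant improvement. Boundary
membership is tested explicitly.

**Coverage classes.** Six left-open right-closed bins on (−0.3, 1]: bare
(−0.3, 0], low (0, 0.2], medium-low (0.2, 0.4], medium (0.4, 0.6],
medium-high (0.6, 0.8], high (0.8, 1]. Values outside (−0.3, 1] error at
the scalar level and are masked-with-count at the map level (`class_map()`).

`class_proportions()` reports every class (absent ones as 0, summing to 1)
and `proportion_trend()` reuses the OLS machinery on the percentage shares,
so a "medium-high share grows by 0.23 points per year" statement is one
call.

**Units.** Slopes are always stored raw (NDVI·yr⁻¹). Published regional
rates for this analysis are sometimes printed in ambiguous scaled units;
only their sign and ordering are treated as reproducible structure.

## 4. Correlation maps

`pixel_correlation()` is Pearson's r, vectorised over cells, with two
masking rules: fewer than `min_years` complete pairs (default 5, chosen so
an 11-year post-break segment tolerates moderate gaps), or zero variance in
either series. Per-pixel two-sided p-values (t on n−2 df) are computed and
stored but never used for masking — the maps show raw r, as is conventional
for these figures. `sign_fractions()` summarises a map as the share of
positively and negatively correlated area; cells exactly at the threshold
count as positive (the boundary convention is stated because published
percentages never define it). Correlations are computed per segment, on
exactly the year ranges `segment()` produces.

## 5. The geographical detector

**Factor detector.** For a response \(y\) stratified by a factor into
\(h = 1..L\) strata,
\[
q = 1 - \frac{\sum_h N_h \delta_h^2}{N \delta^2} = 1 - \mathrm{SSW}/\mathrm{SST},
\]
the fraction of spatial variance explained by the stratification.
*Variance convention:* population (divide-by-count) variances in both
numerator and denominator. Any consistent convention cancels; mixing
sample variance above with population variance below is the classic
implementation bug, and `factor_q()` forecloses it by working with sums of
squares directly.

**Discretization.** Continuous factors are cut by Jenks natural breaks
(`jenks_breaks()`), the exact Fisher dynamic program over contiguous
partitions of the sorted values — not the iterative heuristic that can
stick in local optima. Default k = 5 classes per factor (configurable): the
source analyses do not state their class counts, and 5 is the common
cartographic default. Tied values never split across classes. Stratum
labels use left-closed binning (`stratify()`): a value equal to a threshold
joins the upper stratum. Aspect is treated as categorical (compass sectors):
Jenks on circular degrees is meaningless. Land use is categorical by
nature.

**Sampling.** `sample_points()` draws seeded, distinct random cell centres
and drops any point with a masked value in any layer, reporting the count —
the package's operational definition of "outliers removed", since published
outlier rules for this step are never specified.

**Significance.** The test behind the stars (\*, \*\*, \*\*\* at p < 0.1,
0.05, 0.01) is unspecified in the source literature. The default here is a
seeded permutation test — assumption-free, exact in expectation:
\(p = (1+\#\{q_{perm} \ge q_{obs}\})/(1+n_{perm})\) under random relabeling.
The noncentral-F reference distribution published for the factor detector
(\(F = \frac{N-L}{L-1}\frac{q}{1-q}\), df \(L-1, N-L\), with the standard
noncentrality) is available for comparability with standard Geodetector
software.

**Interaction detector.** `interaction_q()` computes q on the Cartesian
overlay of two stratifications (occupied pairs only).
`classify_interaction()` applies the five-way taxonomy in a fixed order,
with independence decided first under a tolerance \(\varepsilon = 10^{-6}\)
on the q scale (exact equality of floating-point q values is measure-zero).
Note a structural fact: on the *same* sample the overlay refines both
partitions, so \(q_{AB} \ge \max(q_A, q_B)\) up to round-off — "enhancement"
is the generic outcome, and the weakening categories can only arise across
differing samples or discretizations. The package classifies per the
printed taxonomy regardless.

## 6. The synthetic world

`make_scene()` generates everything the pipeline consumes. Its defaults are
the stated world, fixed once:

* **Frame:** 39 years (1982–2020), split year 2009, 30×30 cells at 0.083°.
* **Space:** base NDVI rises NW→SE from 0.45 to 0.80 (regional mean 0.625),
  the canonical arid-to-humid gradient of a high-plateau watershed.
* **Time:** regional anomaly −0.00037·yr⁻¹ before the split (0.63 → 0.62),
  a **level jump of +0.03** at the split, then +0.0027·yr⁻¹ (→ 0.68). The
  explicit jump is deliberate: the ordered-cluster scan detects mean
  shifts, and a pure slope kink is not localisable by it (section 2). The
  jump size is consistent with the regime shifts this method reports in
  practice (a pooled-t statistic of ~5.8 on a 39-year series corresponds to
  a ≈2σ_p mean shift); with it, the noise-free \(S_n\) valley sits exactly
  at the designed split.
* **Noise:** independent Gaussian per cell-year, sd 0.01 NDVI (no error
  model is published for such records; 0.01 at the cell level leaves the
  regional series visually realistic). Half the noise variance
  (`p_coupling = 0.5`) is shared with the precipitation anomaly, so
  NDVI–precipitation correlation maps are positive by design.
* **Sub-monthly composites:** two per month, each the monthly value minus a
  nonnegative uniform "atmospheric" deficit, with one of the two deficit-free
  per cell-month — so MVC recovery is exact in the noise-free limit, and
  the compositing chain is testable against closed-form truth.
* **Drivers:** generated on a half-resolution grid and carried coarse, so
  every end-to-end run exercises the alignment path. Each base field is its
  gradient plus *static* spatial noise sized closed-form so the 5-class q
  ladder against mean NDVI mirrors the magnitudes typical of this analysis:
  precipitation ≈ 0.76 and first, then soil temperature, temperature,
  evapotranspiration, soil moisture, elevation, and near-zero human
  factors. Interannual driver anomalies average out of the period means and
  therefore do not disturb the ladder; they drive the correlation maps
  instead.

`make_regional_series()` draws the regional series the scene implies
(designed path plus regional residual of sd `noise_sd`/√cells) without
building grids, for fast replicate studies; a test asserts the grid route
matches it in distribution.

**What a green test establishes — and does not.** The generator emulates
the *statistical structure* of a real record: gradient, regime shift,
coupled anomalies, stratified drivers. It does not emulate sensor artifacts,
spatially correlated noise (available via an option, off by default),
orbital drift, snow/lake masking, or calendar effects. Green tests
establish that the estimators recover designed structure under the stated
noise model — not that any particular real-world dataset would yield the
same numbers.

## 7. Formats and degenerate inputs

Rasters travel as ESRI ASCII grids (`.asc`, with a `.prj` sidecar for the
CRS): plain text, GDAL/ArcGIS/QGIS-readable, and diff-able. This is a
deliberate substitution — the environment this package targets has no
GeoTIFF-capable R library — and the format carries the same semantics
(transform, nodata tag, CRS). Multi-layer data are one file per layer
(`write_stack()`/`read_stack()`). Values are stored at 15 significant
digits by default, which round-trips doubles in practice.

Alignment (`align()`) is cell-centre based. Nearest neighbour never invents
values and is mandatory for categorical fields; bilinear masks any output
with a masked contributor, and reference cells beyond the outermost source
centres come out masked — conservative at lake/nodata edges and at the
border of coarser driver grids, at the cost of a masked one-cell fringe
(visible as the dropped-point count in detector runs).

Everything downstream excludes masked cells from every statistic; degenerate
cases (all-masked regions, zero-variance responses, constant series,
out-of-range classifications) raise explicit errors rather than returning
silent NA or arbitrary values.
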