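# vegdyn

Vegetation dynamics from long NDVI records: change points, trends, and
driver attribution.

`vegdyn` is for analysts of gridded vegetation-index time series (e.g. a
multi-decade AVHRR/MODIS NDVI record over an alpine watershed) who want to
answer three linked questions in one reproducible chain:

1. **When did the vegetation regime change?** The regional growing-season
   NDVI series is scanned by ordered cluster analysis (OCA): for every
   candidate split year τ the total within-segment sum of squared
   deviations

   S<sub>n</sub>(τ) = Σ<sub>t≤τ</sub>(x<sub>t</sub> − x̄<sub>τ</sub>)² + Σ<sub>t>τ</sub>(x<sub>t</sub> − x̄<sub>n−τ</sub>)²

   is evaluated, the minimising τ\* is the change point, and the mean jump
   across it is tested with the pooled two-sample statistic
   |T| = |x̄<sub>τ</sub> − x̄<sub>n−τ</sub>| / (s<sub>p</sub>·√(1/τ + 1/(n−τ))).
2. **Where and how fast is cover changing?** Per-pixel OLS trends
   θ = (nΣi·x<sub>i</sub> − Σi·Σx<sub>i</sub>)/(nΣi² − (Σi)²) classified
   into five change levels, six-class NDVI coverage maps, class-share time
   series, and per-pixel Pearson correlation maps against climate drivers,
   all segment-aware.
3. **Which drivers explain the spatial pattern?** The Geodetector
   q-statistic, q = 1 − SSW/SST, on Jenks natural-breaks strata of each
   factor, with a seeded permutation test (or the published noncentral-F
   reference) and the five-category interaction taxonomy on pairwise
   stratum overlays.

A synthetic scene generator (`make_scene()`) produces sub-monthly NDVI
composites with a known change point and NW→SE gradient, coarser-grid
climate drivers, and static factors with a designed q ladder, so the whole
chain is testable end to end without downloading any data. Rasters travel
as plain-text ESRI ASCII grids (`.asc` + `.prj` sidecar), readable by GDAL,
ArcGIS and QGIS.

## Worked example

Detect the regime change in a synthetic 39-year scene:

```r
library(vegdyn)
scene  <- make_scene(scene_config(seed = 42))
annual <- composite_annual(scene$ndvi_sub)   # per-month MVC + May–Sep mean of maxima
series <- regional_series(annual)
oca(series)
```

```
Ordered cluster analysis (change-point scan)
  series : 39 years, 1982-2020
  split  : after 2009 (tau* = 28), Sn(tau*) = 0.00105546
  means  : 0.6200 -> 0.6612
  |T| = 21.691 vs 1.645 at alpha = 0.05: significant jump
```

The S<sub>n</sub>(τ) valley sits at 2009 — the scene's designed split — and
the mean jump dwarfs the 1.64 critical value, so the record divides into a
mildly declining 1982–2009 segment and a strongly rising 2010–2020 segment
(`pixel_slope` on the segments: −0.00037 vs +0.0027 NDVI/yr).

Attribute the spatial NDVI pattern to drivers:

```r
template <- annual$grids[[1]]
ymean <- grid_from_cells(template, colMeans(stack_matrix(annual)))
facs  <- c(scene$statics, lapply(scene$drivers, function(d) {
  al <- align_stack(d, template)             # drivers live on a coarser grid
  grid_from_cells(template, colMeans(stack_matrix(al)))
}))
tab <- sample_points(ymean, facs, 800, seed = 42)
geodetector(tab, categorical = c("aspect", "landuse"), n_perm = 199, seed = 42)
```

```
Geographical detector fit (696 points, permutation test)

Factor detector (q, descending):
  P                q = 0.869 *** (p = 0.005, L = 5)
  ST               q = 0.725 *** (p = 0.005, L = 5)
  ETA              q = 0.503 *** (p = 0.005, L = 5)
  T                q = 0.486 *** (p = 0.005, L = 5)
  SM               q = 0.448 *** (p = 0.005, L = 5)
  elevation        q = 0.232 *** (p = 0.005, L = 5)
  popdens          q = 0.050 *** (p = 0.005, L = 5)
  landuse          q = 0.016 *   (p = 0.06, L = 6)
  gdp              q = 0.005     (p = 0.53, L = 5)
  aspect           q = 0.005     (p = 0.865, L = 8)
  slope            q = 0.003     (p = 0.695, L = 5)

Interaction detector: nonlinear enhancement (29), double-factor enhancement (26)
```

Precipitation ranks first (as the scene designs), meteorological factors
dominate the static and human ones, and every pairwise interaction is an
enhancement — the structural consequence of overlay refinement. The 104
dropped points are cells where the coarser driver grids, conservatively
bilinear-aligned, leave the fine-grid border masked.

`run_all(run_config())` chains every stage (compositing → change point →
segmented trend, coverage, correlation, Geodetector) and writes CSV/ASCII
grid/JSON outputs plus a run manifest; reruns under one seed are
byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the complete pipeline on the default synthetic scene under the given
seed — compositing, change-point detection, segmented trend and correlation
mapping, and Geodetector attribution — logs the headline results, and
writes the JSON report to `--out`.
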