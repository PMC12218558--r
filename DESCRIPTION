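Package: vegdyn
Title: Vegetation Dynamics from NDVI Time Series: Change Points, Trends,
    and Driver Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term vegetation dynamics from gridded
    NDVI records: maximum-value compositing of sub-monthly composites into
    growing-season fields, ordered cluster analysis (OCA) change-point
    detection on the regional annual series with a pooled-t jump test,
    per-pixel linear trend estimation and trend/coverage classification,
    per-pixel NDVI-driver Pearson correlation maps, and Geodetector
    factor/interaction attribution (q-statistic on Jenks natural-breaks
    strata, permutation or noncentral-F significance). A synthetic scene
    generator with a designed spatial gradient, change-point year and
    stratified driver structure makes every stage testable without external
    data. Rasters are carried as plain-text ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
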