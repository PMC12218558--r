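#' Ordinary least-squares trend of a series on its time index
#'
#' The per-pixel trend statistic: the OLS slope of the annual values on the
#' index \eqn{i = 1..n},
#' \deqn{\theta = \frac{n \sum i\,x_i - (\sum i)(\sum x_i)}{n \sum i^2 - (\sum i)^2}.}
#' Vectorised over columns so a whole raster stack is fitted in one call.
#'
#' @param x Numeric vector (one series) or matrix with one column per series
#'   and one row per year. `NA`s are allowed per series; a series needs
#'   `min_years` valid years, else its slope is `NA`.
#' @param min_years Minimum valid years per series (default 3).
#' @return Scalar slope, or a vector of slopes (one per column).
#' @export
pixel_slope <- function(x, min_years = 3L) {
  if (is.null(dim(x))) return(pixel_slope(matrix(x, ncol = 1L), min_years)[1L])
  n <- nrow(x)
  i <- seq_len(n)
  ok <- !is.na(x)
  cnt <- colSums(ok)
  iok <- i * ok                      # index where valid, 0 elsewhere
  si <- colSums(iok)
  si2 <- colSums(iok * i)
  xv <- x; xv[!ok] <- 0
  sx <- colSums(xv)
  six <- colSums(xv * i)
  den <- cnt * si2 - si^2
  slope <- (cnt * six - si * sx) / den
  slope[cnt < min_years | den == 0] <- NA_real_
  slope
}

#' Per-pixel trend map of an annual stack
#'
#' @param annual A [vd_stack()] with one grid per year.
#' @param min_years Minimum valid years per cell; cells with fewer come out
#'   masked and are counted in the `n_short` attribute.
#' @return A [vd_grid()] of slopes (value units per year) with attribute
#'   `n_short`, the count of cells masked for insufficient years.
#' @export
slope_map <- function(annual, min_years = 3L) {
  stopifnot(is_vd_stack(annual))
  m <- stack_matrix(annual)
  sl <- pixel_slope(m, min_years = min_years)
  short <- sum(colSums(!is.na(m)) < min_years & colSums(!is.na(m)) > 0)
  g <- grid_from_cells(annual$grids[[1]], sl)
  attr(g, "n_short") <- short
  g
}

# Trend classes (slope theta, NDVI units per year). The printed bins overlap
# at every interior endpoint; the convention here is the unique partition
# consistent with the closed extreme bins (<= -0.0019 and >= 0.0006):
# interior bins are left-open, right-closed on the degradation side and the
# "slight improvement" bin is open at 0.0006.
.trend_levels <- c("obvious degradation", "mild degradation", "basically stable",
                   "slight improvement", "significant improvement")
.trend_breaks <- c(-0.0019, -0.0010, -0.0002, 0.0006)

#' Classify trend slopes into the five change levels
#'
#' Levels and default thresholds (NDVI per year):
#' obvious degradation `<= -0.0019`; mild degradation `(-0.0019, -0.0010]`;
#' basically stable `(-0.0010, -0.0002]`; slight improvement
#' `(-0.0002, 0.0006)`; significant improvement `>= 0.0006`. These form a
#' true partition of the real line; exact boundary membership follows the
#' closed extreme bins.
#'
#' @param theta Numeric vector of slopes; must be finite (NA allowed, passed
#'   through).
#' @return Factor with the five trend levels.
#' @export
classify_trend <- function(theta) {
  if (any(!is.finite(theta) & !is.na(theta)))
    stop("non-finite slope value")
  cls <- rep(NA_integer_, length(theta))
  ok <- !is.na(theta)
  t0 <- theta[ok]
  k <- integer(length(t0))
  k[t0 <= .trend_breaks[1]] <- 1L
  k[t0 > .trend_breaks[1] & t0 <= .trend_breaks[2]] <- 2L
  k[t0 > .trend_breaks[2] & t0 <= .trend_breaks[3]] <- 3L
  k[t0 > .trend_breaks[3] & t0 < .trend_breaks[4]] <- 4L
  k[t0 >= .trend_breaks[4]] <- 5L
  cls[ok] <- k
  factor(.trend_levels[cls], levels = .trend_levels)
}

.coverage_levels <- c("bare", "low", "medium-low", "medium", "medium-high", "high")
.coverage_breaks <- c(-0.3, 0, 0.2, 0.4, 0.6, 0.8, 1)

#' Classify NDVI into the six coverage classes
#'
#' Left-open, right-closed bins on (-0.3, 1]: bare `(-0.3, 0]`, low
#' `(0, 0.2]`, medium-low `(0.2, 0.4]`, medium `(0.4, 0.6]`, medium-high
#' `(0.6, 0.8]`, high `(0.8, 1]`. Values outside `(-0.3, 1]` are an error
#' at this level; map-level wrappers mask and count them.
#'
#' @param ndvi Numeric vector of NDVI values (NA passed through).
#' @return Factor with the six coverage levels.
#' @export
classify_coverage <- function(ndvi) {
  ok <- !is.na(ndvi)
  if (any(ndvi[ok] <= .coverage_breaks[1] | ndvi[ok] > 1))
    stop("NDVI outside (-0.3, 1] cannot be classified")
  out <- cut(ndvi, breaks = .coverage_breaks, labels = .coverage_levels,
             right = TRUE)
  factor(as.character(out), levels = .coverage_levels)
}

#' Class map of a grid under a classifier
#'
#' Applies [classify_trend()] or [classify_coverage()] cell-wise; cells whose
#' value falls outside the classifier's domain are masked and counted.
#'
#' @param grid A [vd_grid()].
#' @param type `"trend"` or `"coverage"`.
#' @return A [vd_grid()] of integer class codes (1-based in level order),
#'   with attributes `levels` (code table) and `n_invalid`.
#' @export
class_map <- function(grid, type = c("trend", "coverage")) {
  stopifnot(is_vd_grid(grid))
  type <- match.arg(type)
  v <- as.vector(grid$values)
  if (type == "coverage") {
    bad <- !is.na(v) & (v <= .coverage_breaks[1] | v > 1)
    v[bad] <- NA_real_
    cls <- classify_coverage(v)
  } else {
    bad <- !is.na(v) & !is.finite(v)
    v[bad] <- NA_real_
    cls <- classify_trend(v)
  }
  g <- grid_from_cells(grid, as.integer(cls))
  attr(g, "levels") <- levels(cls)
  attr(g, "n_invalid") <- sum(bad)
  g
}

#' Per-class fractions of a class map
#'
#' @param class_map A [vd_grid()] of integer class codes carrying a `levels`
#'   attribute (as produced by [class_map()]), or a factor vector.
#' @return Named numeric vector of fractions over unmasked cells; classes
#'   absent from the map report 0 and the fractions sum to 1.
#' @export
class_proportions <- function(class_map) {
  if (is_vd_grid(class_map)) {
    lev <- attr(class_map, "levels")
    if (is.null(lev)) stop("class map lacks a levels attribute")
    f <- factor(lev[as.vector(class_map$values)], levels = lev)
  } else f <- as.factor(class_map)
  f <- f[!is.na(f)]
  if (length(f) == 0L) stop("class_proportions: all cells masked")
  table(f) / length(f)
}

#' Trend of per-class proportions over years
#'
#' OLS slope (via [pixel_slope()]) of each class's percentage share on the
#' year index — the change rate of, e.g., the medium-high-coverage share.
#'
#' @param fractions Matrix or data frame, one row per year, one column per
#'   class, entries as fractions in \[0, 1\].
#' @return Named vector of slopes in percentage points per year.
#' @export
proportion_trend <- function(fractions) {
  m <- as.matrix(fractions) * 100
  if (nrow(m) < 3L) stop("need at least 3 years of proportions")
  stats::setNames(pixel_slope(m), colnames(m))
}
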