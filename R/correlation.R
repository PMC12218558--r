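#' Pearson correlation between paired series
#'
#' The per-pixel association statistic: Pearson's
#' \deqn{r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'   {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}.}
#' Vectorised over columns (one column per pixel). Pairs with a missing
#' value in either series are dropped; a pixel needs at least `min_years`
#' complete pairs and nonzero variance in both series, else `NA`.
#'
#' @param x,y Numeric vectors, or matrices of identical shape (rows = years,
#'   columns = pixels).
#' @param min_years Minimum complete pairs per pixel (default 5 — chosen so
#'   an 11-year post-break segment still correlates under moderate gaps).
#' @return Scalar r, or a vector of r (one per column).
#' @export
pixel_correlation <- function(x, y, min_years = 5L) {
  if (is.null(dim(x)))
    return(pixel_correlation(matrix(x, ncol = 1L), matrix(y, ncol = 1L),
                             min_years)[1L])
  stopifnot(identical(dim(x), dim(y)))
  ok <- !is.na(x) & !is.na(y)
  cnt <- colSums(ok)
  xv <- x; xv[!ok] <- 0
  yv <- y; yv[!ok] <- 0
  sx <- colSums(xv); sy <- colSums(yv)
  sxx <- colSums(xv * xv); syy <- colSums(yv * yv); sxy <- colSums(xv * yv)
  num <- cnt * sxy - sx * sy
  den2 <- (cnt * sxx - sx^2) * (cnt * syy - sy^2)
  r <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
  r[cnt < min_years] <- NA_real_
  # arithmetic round-off can push |r| a hair over 1
  pmin(pmax(r, -1), 1)
}

#' Per-pixel correlation map between an NDVI stack and a driver stack
#'
#' Both stacks must share geometry and time index (align drivers first with
#' [align_stack()]). Per-pixel two-sided p-values from the t reference on
#' n - 2 degrees of freedom are computed and stored but never used for
#' masking: the maps carry raw r.
#'
#' @param ndvi,driver [vd_stack()] objects on one geometry with matching
#'   time labels.
#' @param driver_name Label stored with the result.
#' @param min_years See [pixel_correlation()].
#' @return A list of class `correlation_map`: `r` and `p` grids, `n_years`
#'   grid of complete-pair counts, `driver`, `period`, and `n_insufficient`
#'   (cells masked for too few pairs).
#' @export
correlation_map <- function(ndvi, driver, driver_name = "driver", min_years = 5L) {
  stopifnot(is_vd_stack(ndvi), is_vd_stack(driver))
  if (!same_geometry(ndvi$grids[[1]], driver$grids[[1]]))
    stop("NDVI and driver stacks are not co-registered; align the driver first")
  if (!identical(as.numeric(ndvi$time), as.numeric(driver$time)))
    stop("NDVI and driver stacks differ in time index")
  y <- stack_matrix(ndvi)
  x <- stack_matrix(driver)
  r <- pixel_correlation(x, y, min_years = min_years)
  cnt <- colSums(!is.na(x) & !is.na(y))
  df <- cnt - 2L
  tt <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(is.na(r) | df < 1, NA_real_, 2 * stats::pt(tt, pmax(df, 1), lower.tail = FALSE))
  template <- ndvi$grids[[1]]
  structure(list(
    r = grid_from_cells(template, r),
    p = grid_from_cells(template, p),
    n_years = grid_from_cells(template, cnt),
    driver = driver_name,
    period = range(as.numeric(ndvi$time)),
    n_insufficient = sum(cnt > 0 & cnt < min_years)
  ), class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> NDVI ~ %s, %d-%d\n", x$driver,
              x$period[1], x$period[2]))
  sf <- sign_fractions(x)
  cat(sprintf("  positive %.1f%%, negative %.1f%% of valid cells\n",
              100 * sf["positive"], 100 * sf["negative"]))
  invisible(x)
}

#' Fractions of positively and negatively correlated area
#'
#' The share of unmasked cells with r at or above / below the threshold.
#' Cells exactly at the threshold count as positive (the boundary is not
#' defined by convention elsewhere, so it is fixed here).
#'
#' @param cmap A `correlation_map` (or a [vd_grid()] / numeric vector of r).
#' @param threshold Cutoff separating positive from negative (default 0).
#' @return Named vector `c(positive, negative)`; sums to 1 over valid cells.
#' @export
sign_fractions <- function(cmap, threshold = 0) {
  r <- if (inherits(cmap, "correlation_map")) as.vector(cmap$r$values)
       else if (is_vd_grid(cmap)) as.vector(cmap$values)
       else as.numeric(cmap)
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("sign_fractions: all cells masked")
  c(positive = mean(r >= threshold), negative = mean(r < threshold))
}
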