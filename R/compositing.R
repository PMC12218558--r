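#' Maximum value composite of sub-period grids
#'
#' The per-cell maximum over a set of co-registered composites. MVC is the
#' standard defence against cloud- and atmosphere-depressed NDVI: residual
#' contamination only ever lowers NDVI, so the per-period maximum is the
#' best available estimate of the surface signal. A cell is masked only when
#' it is masked in every input.
#'
#' @param composites A [vd_stack()] of sub-period grids (typically the
#'   sub-monthly composites of one month).
#' @return A [vd_grid()] of per-cell maxima.
#' @export
mvc <- function(composites) {
  stopifnot(is_vd_stack(composites))
  m <- stack_matrix(composites)
  mx <- suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- NA_real_   # all-masked columns give -Inf
  grid_from_cells(composites$grids[[1]], mx)
}

#' Growing-season compositing configuration
#'
#' @param season_months Integer months of the growing season (default May
#'   through September).
#' @param mode How monthly maxima are combined into the annual field:
#'   `"monthly_max_mean"` (mean of the monthly maxima — the default reading
#'   of "average of the maximum NDVI values" over the season) or
#'   `"seasonal_max"` (single maximum over the whole season). One mode must
#'   be used consistently within a run.
#' @return A list of class `composite_config`.
#' @export
composite_config <- function(season_months = 5:9,
                             mode = c("monthly_max_mean", "seasonal_max")) {
  if (length(season_months) == 0L) stop("season_months must be nonempty")
  structure(list(season_months = as.integer(season_months),
                 mode = match.arg(mode)),
            class = "composite_config")
}

#' Annual growing-season NDVI field from monthly maxima
#'
#' @param monthly_max A [vd_stack()] holding one monthly-MVC grid per season
#'   month; `time` labels are month numbers.
#' @param config A [composite_config()].
#' @return A [vd_grid()]: per-cell mean of the monthly maxima
#'   (`monthly_max_mean`) or per-cell seasonal maximum (`seasonal_max`).
#'   Cells masked in every month stay masked; under `monthly_max_mean` the
#'   mean is over the months valid at that cell.
#' @export
growing_season_ndvi <- function(monthly_max, config = composite_config()) {
  stopifnot(is_vd_stack(monthly_max), inherits(config, "composite_config"))
  missing_m <- setdiff(config$season_months, as.integer(monthly_max$time))
  if (length(missing_m) > 0L)
    stop("missing season months: ", paste(missing_m, collapse = ", "))
  keep <- as.integer(monthly_max$time) %in% config$season_months
  m <- stack_matrix(monthly_max)[keep, , drop = FALSE]
  out <- if (config$mode == "monthly_max_mean") {
    colMeans(m, na.rm = TRUE)
  } else {
    suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
  }
  out[!is.finite(out)] <- NA_real_
  grid_from_cells(monthly_max$grids[[1]], out)
}

#' Regional mean of a grid
#'
#' Unweighted mean over unmasked cells, optionally restricted to the cells
#' where `mask` is unmasked and nonzero (e.g. a watershed boundary raster).
#' An optional latitude-cosine weighting is available for wide-latitude
#' domains but is off by default.
#'
#' @param grid A [vd_grid()].
#' @param mask Optional [vd_grid()] on the same geometry; cells where it is
#'   `NA` or 0 are excluded.
#' @param lat_weight If `TRUE`, weight cells by the cosine of their centre
#'   latitude (assumes geographic coordinates in degrees).
#' @return Scalar mean.
#' @export
regional_mean <- function(grid, mask = NULL, lat_weight = FALSE) {
  stopifnot(is_vd_grid(grid))
  v <- grid$values
  if (!is.null(mask)) {
    stopifnot(is_vd_grid(mask))
    if (!same_geometry(grid, mask)) stop("mask geometry differs from grid")
    v[is.na(mask$values) | mask$values == 0] <- NA_real_
  }
  ok <- !is.na(v)
  if (!any(ok)) stop("regional_mean: no valid cells")
  if (!lat_weight) return(mean(v[ok]))
  w <- matrix(cos(grid_coords(grid)$y * pi / 180), nrow(v), ncol(v))
  sum(v[ok] * w[ok]) / sum(w[ok])
}

#' Regional annual series from an annual stack
#'
#' Applies [regional_mean()] to every layer, giving the annual series that
#' feeds the change-point analysis.
#'
#' @param annual A [vd_stack()] with one grid per year and years as `time`.
#' @inheritParams regional_mean
#' @return An [annual_series()].
#' @export
regional_series <- function(annual, mask = NULL, lat_weight = FALSE) {
  stopifnot(is_vd_stack(annual))
  vals <- vapply(annual$grids, regional_mean, numeric(1),
                 mask = mask, lat_weight = lat_weight)
  annual_series(as.integer(annual$time), vals)
}
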