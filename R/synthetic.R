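#' Configuration of the synthetic vegetation scene
#'
#' The generator's stated world mirrors the structure of a long alpine NDVI
#' record: a 39-year span with a regime change in 2009, growing-season
#' regional means between 0.62 and 0.68, a base NDVI rising along the
#' NW-to-SE diagonal, and a precipitation field sharing that gradient so its
#' stratification explains most of the spatial NDVI variance by
#' construction.
#'
#' The regional annual mean follows `slope_before` up to `split_year`, then
#' jumps by `jump` and follows `slope_after`. The explicit level shift is
#' what the ordered-cluster scan detects: a pure slope kink has no mean jump
#' and the two-mean split criterion does not localise it, so a generator
#' meant to be recovered by OCA must shift the mean. Defaults: a mild
#' decline 0.63 to 0.62 over 1982-2009, a 0.03 jump, then a rise to 0.68 by
#' 2020 — the regime change a significant pooled-t jump implies.
#'
#' Per-cell interannual noise has standard deviation `noise_sd`, of which a
#' fraction `sqrt(p_coupling)` of variance is shared with the precipitation
#' anomaly, so NDVI-precipitation correlation maps are positive by design.
#'
#' @param nrow,ncol Grid shape.
#' @param years Year span (default 1982:2020, n = 39).
#' @param split_year Designed change point (strictly inside the span).
#' @param slope_before,slope_after Regional trends per segment (NDVI/year).
#' @param jump Level shift at the split (NDVI units).
#' @param gradient Base-NDVI range along the NW-to-SE diagonal.
#' @param noise_sd Per-cell interannual noise sd (NDVI units).
#' @param p_coupling Fraction of per-cell noise variance shared with the
#'   precipitation anomaly (0..1).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(nrow = 30L, ncol = 30L, years = 1982:2020,
                         split_year = 2009L, slope_before = -0.00037,
                         slope_after = 0.0027, jump = 0.03,
                         gradient = c(0.45, 0.80), noise_sd = 0.01,
                         p_coupling = 0.5, seed = 1L) {
  if (split_year <= years[1] || split_year >= years[length(years)])
    stop("split_year must lie strictly inside the year span")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(gradient <= 0) || any(gradient >= 1) || gradient[2] <= gradient[1])
    stop("gradient must be an increasing range inside (0, 1)")
  if (p_coupling < 0 || p_coupling > 1) stop("p_coupling must lie in [0, 1]")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 years = as.integer(years), split_year = as.integer(split_year),
                 slope_before = slope_before, slope_after = slope_after,
                 jump = jump, gradient = gradient, noise_sd = noise_sd,
                 p_coupling = p_coupling, seed = as.integer(seed)),
            class = "scene_config")
}

# Designed regional anomaly (relative to the base surface) per year.
scene_trend <- function(config) {
  yrs <- config$years
  t0 <- yrs[1]; sp <- config$split_year
  ifelse(yrs <= sp,
         config$slope_before * (yrs - t0),
         config$slope_before * (sp - t0) + config$jump +
           config$slope_after * (yrs - sp))
}

#' Designed regional annual series of a scene (no grids built)
#'
#' The regional-mean NDVI series the scene implies, drawn directly: the
#' designed piecewise trend plus the regional residual of the per-cell
#' noise, whose standard deviation is `noise_sd / sqrt(nrow * ncol)`. Used
#' for fast replicate studies of change-point recovery; the full
#' [make_scene()] regional series has the same distribution.
#'
#' @param config A [scene_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An [annual_series()].
#' @export
make_regional_series <- function(config = scene_config(), seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  seed <- if (is.null(seed)) config$seed else seed
  mu <- mean(config$gradient) + scene_trend(config)
  sd_reg <- config$noise_sd / sqrt(config$nrow * config$ncol)
  vals <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd_reg))
  annual_series(config$years, vals)
}

#' Generate the full synthetic input scene
#'
#' Builds everything the pipeline consumes, on formats indistinguishable
#' from real input:
#' \itemize{
#'   \item `ndvi_sub`: sub-monthly NDVI composites (two per growing-season
#'     month, May-September), each the monthly value minus a nonnegative
#'     "atmospheric" deficit; per cell and month one of the two composites
#'     is deficit-free, so maximum-value compositing recovers the monthly
#'     value exactly. A `calendar` attribute (`year`, `month`, `sub`)
#'     indexes the layers.
#'   \item `drivers`: annual precipitation, temperature, soil moisture, soil
#'     temperature and actual-evapotranspiration stacks. They are generated
#'     on a grid of half the NDVI resolution and carried at that coarse
#'     geometry, so consumers must run them through [align_stack()] — the
#'     alignment path is exercised by every end-to-end run. The
#'     precipitation base field shares the NDVI diagonal gradient and its
#'     interannual anomaly is the coupled component of the NDVI noise.
#'   \item `statics`: elevation (high NW, low SE, with terrain noise),
#'     slope, aspect sector (categorical 1-8), land-use class (categorical),
#'     GDP and population density, on the NDVI geometry.
#' }
#'
#' @param config A [scene_config()].
#' @return A list of class `vd_scene` with elements `ndvi_sub`, `drivers`,
#'   `statics`, `config`, and `design` (the noise-free regional series).
#' @export
make_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$nrow; nc <- config$ncol
  yrs <- config$years; ny <- length(yrs)
  template <- vd_grid(matrix(0, nr, nc), xmin = 95.9, ymin = 32.2,
                      dx = 0.083, crs = "EPSG:4326")
  # NW (row 1, col 1) low, SE high
  rowf <- matrix((seq_len(nr) - 1) / max(nr - 1, 1), nr, nc)
  colf <- matrix((seq_len(nc) - 1) / max(nc - 1, 1), nr, nc, byrow = TRUE)
  diagf <- (rowf + colf) / 2
  base <- config$gradient[1] + diff(config$gradient) * diagf
  trend <- scene_trend(config)

  # coarse geometry for the drivers (half resolution, same extent)
  cr <- max(2L, nr %/% 2L); cc <- max(2L, nc %/% 2L)
  coarse <- vd_grid(matrix(0, cr, cc), xmin = template$xmin, ymin = template$ymin,
                    dx = nc * template$dx / cc, dy = nr * template$dy / cr,
                    crs = template$crs)
  crowf <- matrix((seq_len(cr) - 1) / max(cr - 1, 1), cr, cc)
  ccolf <- matrix((seq_len(cc) - 1) / max(cc - 1, 1), cr, cc, byrow = TRUE)
  cdiag <- (crowf + ccolf) / 2

  seas <- c(-0.06, -0.01, 0.03, 0.05, -0.01)   # May..Sep offsets, zero mean
  months <- 5:9
  rho <- sqrt(config$p_coupling)

  with_seed(config$seed, {
    annual_vals <- vector("list", ny)
    z_coarse <- vector("list", ny)        # precipitation anomaly, coarse
    for (t in seq_len(ny)) {
      z <- matrix(stats::rnorm(nr * nc), nr, nc)      # coupled anomaly (fine)
      e <- matrix(stats::rnorm(nr * nc), nr, nc)      # independent noise
      annual_vals[[t]] <- base + trend[t] +
        config$noise_sd * (rho * z + sqrt(1 - rho^2) * e)
      zc <- align(vd_grid(z, template$xmin, template$ymin, template$dx,
                          template$dy, template$crs), coarse, "bilinear")
      z_coarse[[t]] <- zc$values
    }
    sub_grids <- list()
    calendar <- data.frame(year = integer(0), month = integer(0), sub = integer(0))
    for (t in seq_len(ny)) for (m in seq_along(months)) {
      monthly <- annual_vals[[t]] + seas[m]
      d <- matrix(stats::runif(nr * nc, 0, 0.15), nr, nc)
      clean_first <- matrix(stats::runif(nr * nc) < 0.5, nr, nc)
      d1 <- ifelse(clean_first, 0, d)
      d2 <- ifelse(clean_first, d, 0)
      for (s in 1:2) {
        sub_grids[[length(sub_grids) + 1L]] <-
          grid_from_cells(template, monthly - (if (s == 1L) d1 else d2))
        calendar <- rbind(calendar,
                          data.frame(year = yrs[t], month = months[m], sub = s))
      }
    }
    # Driver design: each base field is its gradient plus STATIC spatial
    # noise (drawn once, constant over years) sized so that the q of its
    # 5-class stratification against mean NDVI approximates the target
    # ladder: P ~0.76 first, then ST ~0.55, T ~0.53, ETA ~0.51, SM ~0.26.
    # Interannual anomalies average out of the period means and so do not
    # enter q; they drive the correlation maps instead.
    mk_driver <- function(base_c, static_sd, anom_sd, shared = FALSE, lo = NULL) {
      b <- base_c + matrix(stats::rnorm(cr * cc, 0, static_sd), cr, cc)
      if (!is.null(lo)) b <- pmax(b, lo)
      grids <- vector("list", ny)
      for (t in seq_len(ny)) {
        anom <- if (shared) anom_sd * z_coarse[[t]]
                else matrix(stats::rnorm(cr * cc, 0, anom_sd), cr, cc)
        grids[[t]] <- grid_from_cells(coarse, b + anom)
      }
      vd_stack(grids, time = yrs)
    }
    drivers <- list(
      P  = mk_driver(480 + 670 * cdiag, 68, 40, shared = TRUE, lo = 0),
      T  = mk_driver(-8 + 12 * ccolf, 0.3, 0.5),
      SM = mk_driver(0.30 + 0.30 * cdiag, 0.10, 0.02, lo = 0.01),
      ST = mk_driver(-6 + 10 * cdiag, 1.75, 0.6),
      ETA = mk_driver(250 + 380 * ccolf, 25, 20, lo = 0)
    )
    statics <- list(
      elevation = grid_from_cells(template,
        6000 - 3500 * diagf + matrix(stats::rnorm(nr * nc, 0, 1400), nr, nc)),
      slope = grid_from_cells(template,
        pmax(abs(matrix(stats::rnorm(nr * nc, 5, 3), nr, nc)), 0.1)),
      aspect = grid_from_cells(template,
        matrix(sample.int(8L, nr * nc, replace = TRUE), nr, nc)),
      landuse = grid_from_cells(template,
        matrix(sample.int(6L, nr * nc, replace = TRUE,
                          prob = c(0.45, 0.25, 0.12, 0.08, 0.06, 0.04)), nr, nc)),
      gdp = grid_from_cells(template,
        exp(matrix(stats::rnorm(nr * nc, 0, 1), nr, nc))),
      popdens = grid_from_cells(template,
        pmax(5 + 10 * colf + matrix(stats::rnorm(nr * nc, 0, 10), nr, nc), 0))
    )
    ndvi_sub <- vd_stack(sub_grids, time = seq_along(sub_grids))
    attr(ndvi_sub, "calendar") <- calendar
    structure(list(
      ndvi_sub = ndvi_sub,
      drivers = drivers,
      statics = statics,
      config = config,
      design = annual_series(yrs, mean(config$gradient) + trend)
    ), class = "vd_scene")
  })
}

#' @export
print.vd_scene <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<vd_scene> %dx%d cells, %d-%d, designed split %d\n",
              cfg$nrow, cfg$ncol, cfg$years[1], cfg$years[length(cfg$years)],
              cfg$split_year))
  cat(sprintf("  %d sub-monthly NDVI layers, %d drivers (coarse), %d static factors\n",
              length(x$ndvi_sub), length(x$drivers), length(x$statics)))
  invisible(x)
}

#' Annual growing-season stack from a scene's sub-monthly layers
#'
#' Runs the compositing chain: per-month [mvc()] of the sub-monthly
#' composites, then [growing_season_ndvi()] per year.
#'
#' @param ndvi_sub Sub-monthly [vd_stack()] carrying a `calendar` attribute
#'   (`year`, `month`, `sub` per layer), as produced by [make_scene()].
#' @param config A [composite_config()].
#' @return A [vd_stack()] with one growing-season grid per year.
#' @export
composite_annual <- function(ndvi_sub, config = composite_config()) {
  cal <- attr(ndvi_sub, "calendar")
  if (is.null(cal)) stop("sub-monthly stack lacks a calendar attribute")
  years <- sort(unique(cal$year))
  annual <- lapply(years, function(yy) {
    monthly <- lapply(config$season_months, function(mm) {
      idx <- which(cal$year == yy & cal$month == mm)
      if (length(idx) == 0L) return(NULL)
      mvc(vd_stack(ndvi_sub$grids[idx], time = seq_along(idx)))
    })
    present <- !vapply(monthly, is.null, logical(1))
    if (!all(present))
      stop("year ", yy, " missing season months: ",
           paste(config$season_months[!present], collapse = ", "))
    growing_season_ndvi(vd_stack(monthly, time = config$season_months), config)
  })
  vd_stack(annual, time = years)
}

#' Stratified response with a designed q
#'
#' Draws stratum means with between-stratum variance `sigma_b^2` and
#' within-stratum noise `sigma_w^2` scaled so that
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2) = target_q`; the sample q of
#' [factor_q()] converges to `target_q` as n grows. Stratum mean offsets are
#' fixed equally spaced (not redrawn per seed) so the designed
#' between-stratum variance is exact, not itself a random draw.
#'
#' @param strata Stratum labels (length n).
#' @param target_q Designed q in \[0, 1). Requesting exactly 1 is an error:
#'   a q of 1 means zero within-stratum noise, obtained deterministically as
#'   the stratum-mean vector itself, and silently degenerate randomness is
#'   worse than an explicit refusal.
#' @param seed Integer seed.
#' @param sigma_w Optional override of the within-stratum noise sd; pass 0
#'   for the zero-noise path, which yields a sample q of exactly 1.
#' @return Numeric response vector of length `length(strata)`.
#' @export
make_stratified_response <- function(strata, target_q, seed = 1L, sigma_w = NULL) {
  if (target_q < 0 || target_q >= 1)
    stop("target_q must lie in [0, 1); q = 1 needs zero within-stratum noise (sigma_w = 0)")
  f <- factor(strata)
  L <- nlevels(f)
  if (L < 2L && target_q > 0) stop("need >= 2 occupied strata for target_q > 0")
  # equally spaced stratum means, standardised to population variance 1
  mu <- seq_len(L) - (L + 1) / 2
  Nh <- as.numeric(table(f))
  w <- Nh / sum(Nh)
  mu <- mu - sum(w * mu)
  vb <- sum(w * mu^2)
  mu <- if (vb > 0) mu / sqrt(vb) else mu
  sigma_b <- sqrt(target_q)
  if (is.null(sigma_w)) sigma_w <- sqrt(1 - target_q)
  with_seed(seed,
            sigma_b * mu[f] + stats::rnorm(length(f), 0, sigma_w))
}

#' Deterministic toy series for oracle tests
#'
#' @param kind `"step"` (levels `params[1]`, `params[2]`, split at `n/2`),
#'   `"ramp"` (`1..n`), or `"constant"` (`params[1]` everywhere).
#' @param n Length (at least 4).
#' @param params Numeric parameters, see `kind`.
#' @param start_year First year of the series.
#' @return An [annual_series()].
#' @export
make_toy_series <- function(kind = c("step", "ramp", "constant"), n = 6L,
                            params = c(0, 10), start_year = 2001L) {
  kind <- match.arg(kind)
  if (n < 4L) stop("n must be at least 4")
  vals <- switch(kind,
    step = c(rep(params[1], n %/% 2), rep(params[2], n - n %/% 2)),
    ramp = as.double(seq_len(n)),
    constant = rep(params[1], n))
  annual_series(start_year + seq_len(n) - 1L, vals)
}
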