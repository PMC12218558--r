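#' Pipeline run configuration
#'
#' One object holding every knob of an end-to-end run, so a run is fully
#' described by (config, seed) and reruns are byte-identical. All randomness
#' is seeded from `seed`.
#'
#' @param scene A [scene_config()] for synthetic mode, or `NULL` when
#'   `inputs` supplies real data.
#' @param inputs Real-mode inputs: a list with `ndvi_sub` (sub-monthly
#'   [vd_stack()] with a `calendar` attribute), `drivers` (named list of
#'   annual [vd_stack()]s, any geometry — they are aligned to the NDVI
#'   geometry), and `statics` (named list of [vd_grid()]s).
#' @param compositing A [composite_config()].
#' @param alpha Change-point test level.
#' @param min_years Minimum complete pairs for per-pixel correlation.
#' @param k_classes Jenks class count per continuous detector factor.
#' @param n_points Detector sample size; default the smaller of 1678 (the
#'   classic fishnet size for this analysis) and 90% of the cell count.
#' @param n_perm Permutations for detector significance.
#' @param categorical Static factors treated as categorical.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), inputs = NULL,
                       compositing = composite_config(), alpha = 0.05,
                       min_years = 5L, k_classes = 5L, n_points = NULL,
                       n_perm = 999L, categorical = c("aspect", "landuse"),
                       seed = 1L) {
  structure(list(scene = scene, inputs = inputs, compositing = compositing,
                 alpha = alpha, min_years = min_years, k_classes = k_classes,
                 n_points = n_points, n_perm = n_perm,
                 categorical = categorical, seed = as.integer(seed)),
            class = "run_config")
}

write_csv0 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full vegetation-dynamics pipeline
#'
#' Executes, in order: compositing (per-month MVC, growing-season annual
#' fields), the regional annual series, ordered-cluster change-point
#' detection, segmentation at the detected split, per-segment trend maps
#' with trend-class proportions, per-year coverage-class proportions and
#' their trends, per-segment NDVI-driver correlation maps with
#' positive/negative area fractions, and per-segment Geodetector
#' factor/interaction attribution. Every stage's tables go to `out_dir` as
#' CSV/ASCII-grid/JSON files and a JSON manifest records the configuration,
#' seeds, per-stage status and dropped-cell/point counts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the manifest list; its `results` element holds the
#'   in-memory stage results (`oca` fit, trend maps, correlation summaries,
#'   `geodetector` fits).
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("vegdyn_run_"),
                    seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log <<- c(log, name)
    res
  }

  # --- inputs -------------------------------------------------------------
  scene <- if (is.null(config$inputs)) {
    sc <- config$scene
    sc$seed <- config$seed
    stage("simulate", make_scene(sc))
  } else {
    log <- c(log, "load")
    config$inputs
  }

  # --- compositing --------------------------------------------------------
  annual <- stage("composite", composite_annual(scene$ndvi_sub, config$compositing))
  template <- annual$grids[[1]]
  series <- regional_series(annual)
  write_csv0(data.frame(year = series$year, value = series$value),
             file.path(out_dir, "regional_series.csv"))

  # --- change point -------------------------------------------------------
  fit <- stage("changepoint", oca(series, alpha = config$alpha))
  jsonlite::write_json(
    list(split_year = fit$split_year, tau_star = fit$tau_star,
         mean_before = fit$mean_before, mean_after = fit$mean_after,
         t_stat = fit$t_stat, critical = fit$critical,
         significant = fit$significant,
         no_change_point = fit$no_change_point,
         tied_taus = fit$tied_taus, secondary_minima = fit$secondary_minima,
         sn_curve = fit$sn_curve),
    file.path(out_dir, "changepoint.json"), auto_unbox = TRUE, digits = NA)
  split_year <- fit$split_year
  periods <- list(
    before = which(as.integer(annual$time) <= split_year),
    after = which(as.integer(annual$time) > split_year)
  )
  sub_stack <- function(idx) vd_stack(annual$grids[idx], time = annual$time[idx])

  # --- trend + coverage ---------------------------------------------------
  trend <- stage("trend", {
    res <- list()
    for (p in names(periods)) {
      st <- sub_stack(periods[[p]])
      sl <- slope_map(st)
      cm <- class_map(sl, "trend")
      write_grid(sl, file.path(out_dir, sprintf("slope_%s.asc", p)))
      write_grid(cm, file.path(out_dir, sprintf("trend_class_%s.asc", p)))
      res[[p]] <- list(slope = sl, class = cm,
                       proportions = class_proportions(cm),
                       mean_slope = mean(sl$values, na.rm = TRUE))
    }
    cov_frac <- t(vapply(seq_along(annual$grids), function(i)
      as.numeric(class_proportions(class_map(annual$grids[[i]], "coverage"))),
      numeric(length(.coverage_levels))))
    colnames(cov_frac) <- .coverage_levels
    write_csv0(data.frame(year = as.integer(annual$time), cov_frac,
                          check.names = FALSE),
               file.path(out_dir, "coverage_proportions.csv"))
    res$coverage <- list(fractions = cov_frac,
                         trend = proportion_trend(cov_frac))
    res
  })

  # --- correlation --------------------------------------------------------
  correlation <- stage("correlate", {
    rows <- list()
    maps <- list()
    for (dn in names(scene$drivers)) {
      drv <- scene$drivers[[dn]]
      if (!same_geometry(drv$grids[[1]], template))
        drv <- align_stack(drv, template, "bilinear")
      for (p in names(periods)) {
        idx <- periods[[p]]
        cmap <- correlation_map(sub_stack(idx),
                                vd_stack(drv$grids[idx], time = drv$time[idx]),
                                driver_name = dn, min_years = config$min_years)
        write_grid(cmap$r, file.path(out_dir, sprintf("r_%s_%s.asc", dn, p)))
        sf <- sign_fractions(cmap)
        rows[[length(rows) + 1L]] <- data.frame(
          driver = dn, period = p,
          pct_positive = 100 * sf[["positive"]],
          pct_negative = 100 * sf[["negative"]],
          n_insufficient = cmap$n_insufficient)
        maps[[paste(dn, p, sep = "_")]] <- cmap
      }
    }
    summary <- do.call(rbind, rows)
    write_csv0(summary, file.path(out_dir, "correlation_summary.csv"))
    list(summary = summary, maps = maps)
  })

  # --- geodetector --------------------------------------------------------
  detector <- stage("detect", {
    n_cells <- length(template$values)
    n_pts <- config$n_points %||% min(1678L, as.integer(0.9 * n_cells))
    res <- list()
    for (p in names(periods)) {
      idx <- periods[[p]]
      ymean <- grid_from_cells(template,
        colMeans(stack_matrix(sub_stack(idx)), na.rm = FALSE))
      facs <- scene$statics
      for (dn in names(scene$drivers)) {
        drv <- scene$drivers[[dn]]
        if (!same_geometry(drv$grids[[1]], template))
          drv <- align_stack(drv, template, "bilinear")
        facs[[dn]] <- grid_from_cells(template,
          colMeans(stack_matrix(vd_stack(drv$grids[idx], time = drv$time[idx]))))
      }
      tab <- sample_points(ymean, facs, n = n_pts,
                           seed = config$seed + match(p, names(periods)))
      write_csv0(as.data.frame(tab), file.path(out_dir, sprintf("samples_%s.csv", p)))
      gd <- geodetector(tab, k = config$k_classes,
                        categorical = config$categorical,
                        n_perm = config$n_perm, seed = config$seed + 100L)
      write_csv0(gd$factor_table, file.path(out_dir, sprintf("detector_q_%s.csv", p)))
      write_csv0(as.data.frame(gd$interaction_q),
                 file.path(out_dir, sprintf("interaction_q_%s.csv", p)))
      res[[p]] <- gd
    }
    res
  })

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "vegdyn",
    seed = config$seed,
    mode = if (is.null(config$inputs)) "synthetic" else "real",
    compositing_mode = config$compositing$mode,
    alpha = config$alpha,
    stages = log,
    changepoint = list(split_year = fit$split_year, t_stat = fit$t_stat,
                       significant = fit$significant),
    mean_slope = lapply(trend[c("before", "after")], function(x) x$mean_slope),
    detector_top_factor = lapply(detector, function(g)
      g$factor_table$factor[which.max(g$factor_table$q)]),
    counts = list(
      detector_points_dropped = lapply(detector, function(g) g$n_dropped),
      correlation_insufficient = sum(correlation$summary$n_insufficient))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- list(oca = fit, trend = trend, correlation = correlation,
                           detector = detector, series = series,
                           annual = annual, out_dir = out_dir)
  invisible(manifest)
}
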