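#' Read a grid from an ESRI ASCII raster file
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a six-line plain-text
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` or
#' `dx`/`dy`, `NODATA_value`) followed by rows of cell values, north first.
#' The format is understood by GDAL, ArcGIS and QGIS. A sidecar `.prj` file,
#' if present, supplies the CRS string; a file with neither a georeference
#' header nor default-able fields is rejected rather than silently assigned
#' an identity transform.
#'
#' @param path Path to the `.asc` file.
#' @param band Band index. ESRI ASCII grids are single-band; any value other
#'   than 1 is an error. Multi-layer data are handled as stacks of files, see
#'   [read_stack()].
#' @return A [vd_grid()] with nodata cells set to `NA`.
#' @seealso [write_grid()], [read_stack()]
#' @export
read_grid <- function(path, band = 1L) {
  if (!file.exists(path)) stop("cannot read grid: no such file: ", path)
  if (band != 1L)
    stop("ESRI ASCII grids are single-band; got band = ", band,
         " (use read_stack() for multi-layer data)")
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "dx", "dy", "nodata_value", "xllcenter", "yllcenter")) {
      hdr[[key]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("missing georeference in ", path, ": header lacks ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (!is.null(hdr$cellsize)) {
    dx <- hdr$cellsize; dy <- hdr$cellsize
  } else if (!is.null(hdr$dx) && !is.null(hdr$dy)) {
    dx <- hdr$dx; dy <- hdr$dy
  } else stop("missing georeference in ", path, ": no cellsize (or dx/dy)")
  nodata <- if (is.null(hdr$nodata_value)) NA_real_ else hdr$nodata_value
  vals <- scan(text = paste(lines[-seq_len(nhdr)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("grid body of ", path, " has ", length(vals), " values, expected ", nc * nr)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  prj <- sub("\\.[^.]*$", ".prj", path)
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE), collapse = "\n")
         else NA_character_
  vd_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner, dx = dx, dy = dy, crs = crs)
}

#' Write a grid to an ESRI ASCII raster file
#'
#' The nodata tag is always written; masked (`NA`) cells are stored as the
#' nodata value. Values are stored with `digits` significant digits
#' (default 15, which round-trips doubles in practice). A `.prj` sidecar is
#' written when the grid carries a CRS.
#'
#' @param grid A [vd_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Nodata sentinel written to the file. Must not collide with a
#'   valid cell value.
#' @param digits Significant digits stored.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path, nodata = -9999, digits = 15) {
  stopifnot(is_vd_grid(grid))
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("nodata sentinel ", nodata, " collides with a valid cell value")
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.15g", grid$xmin),
    sprintf("yllcorner %.15g", grid$ymin),
    if (isTRUE(all.equal(grid$dx, grid$dy)))
      sprintf("cellsize %.15g", grid$dx)
    else c(sprintf("dx %.15g", grid$dx), sprintf("dy %.15g", grid$dy)),
    sprintf("NODATA_value %.15g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  if (!is.na(grid$crs))
    writeLines(grid$crs, sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}

#' Read or write a multi-layer stack as one ASCII grid per layer
#'
#' Layers live in `dir` as `<name>_<label>.asc`; labels double as the time
#' index. `read_stack()` restores them in label order (numeric if all labels
#' parse as numbers).
#'
#' @param stack A [vd_stack()].
#' @param dir Directory holding the layer files.
#' @param name Base name shared by the layer files.
#' @return `write_stack()` the file paths, invisibly; `read_stack()` a
#'   [vd_stack()].
#' @export
write_stack <- function(stack, dir, name) {
  stopifnot(is_vd_stack(stack))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s.asc", name, stack$time))
  for (i in seq_along(paths)) write_grid(stack$grids[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir, name) {
  files <- list.files(dir, pattern = paste0("^", name, "_.*\\.asc$"),
                      full.names = TRUE)
  if (length(files) == 0L) stop("no layers matching '", name, "_*.asc' in ", dir)
  labels <- sub("\\.asc$", "", sub(paste0("^", name, "_"), "", basename(files)))
  num <- suppressWarnings(as.numeric(labels))
  ord <- if (!anyNA(num)) order(num) else order(labels)
  time <- if (!anyNA(num)) num[ord] else labels[ord]
  vd_stack(lapply(files[ord], read_grid), time = time)
}
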