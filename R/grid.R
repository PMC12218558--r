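#' Georeferenced grid container
#'
#' A `vd_grid` is the basic raster unit of the package: a numeric matrix of
#' cell values plus an affine georeference (lower-left corner, cell sizes,
#' coordinate reference string). Row 1 is the northernmost row and cells are
#' centre-registered: the centre of cell `[i, j]` sits at
#' `x = xmin + (j - 0.5) * dx`, `y = ymin + (nrow - i + 0.5) * dy`.
#' Missing data are carried as `NA` and excluded from every downstream
#' statistic.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid extent.
#' @param dx,dy Cell sizes in x and y; both must be positive. `dy` defaults
#'   to `dx` (square cells).
#' @param crs Coordinate reference identifier (free-form string, e.g. a WKT
#'   or "EPSG:4326"), or `NA` if unknown.
#' @return An object of class `vd_grid`.
#' @examples
#' g <- vd_grid(matrix(runif(12), 3, 4), xmin = 95.9, ymin = 32.2, dx = 0.083)
#' g
#' @export
vd_grid <- function(values, xmin = 0, ymin = 0, dx = 1, dy = dx, crs = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("cell sizes dx, dy must be positive")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, dx = dx, dy = dy,
         crs = as.character(crs)),
    class = "vd_grid"
  )
}

#' @export
print.vd_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vd_grid> %d rows x %d cols, cell %g x %g\n", d[1], d[2], x$dx, x$dy))
  cat(sprintf("  extent : x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + d[2] * x$dx, x$ymin, x$ymin + d[1] * x$dy))
  cat(sprintf("  crs    : %s\n", ifelse(is.na(x$crs), "<unset>", x$crs)))
  nv <- sum(!is.na(x$values))
  cat(sprintf("  values : %d valid / %d cells", nv, length(x$values)))
  if (nv > 0)
    cat(sprintf(", range [%g, %g]", min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

is_vd_grid <- function(x) inherits(x, "vd_grid")

#' Cell-centre coordinates of a grid
#'
#' @param grid A [vd_grid()].
#' @return A list with components `x` (length `ncol`) and `y` (length `nrow`,
#'   ordered north to south to match the value matrix rows).
#' @export
grid_coords <- function(grid) {
  stopifnot(is_vd_grid(grid))
  d <- dim(grid$values)
  list(
    x = grid$xmin + (seq_len(d[2]) - 0.5) * grid$dx,
    y = grid$ymin + (d[1] - seq_len(d[1]) + 0.5) * grid$dy
  )
}

grid_extent <- function(grid) {
  d <- dim(grid$values)
  c(xmin = grid$xmin, xmax = grid$xmin + d[2] * grid$dx,
    ymin = grid$ymin, ymax = grid$ymin + d[1] * grid$dy)
}

#' Do two grids share the same geometry?
#'
#' Shape, origin, cell size and CRS are compared (origin and cell size to a
#' relative tolerance of 1e-9).
#'
#' @param a,b Two [vd_grid()] objects.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  stopifnot(is_vd_grid(a), is_vd_grid(b))
  near <- function(u, v) isTRUE(abs(u - v) <= 1e-9 * max(1, abs(u), abs(v)))
  identical(dim(a$values), dim(b$values)) &&
    near(a$xmin, b$xmin) && near(a$ymin, b$ymin) &&
    near(a$dx, b$dx) && near(a$dy, b$dy)
}

#' Time-ordered stack of grids on one common geometry
#'
#' @param grids List of [vd_grid()] objects sharing one geometry.
#' @param time Numeric or character labels, one per grid (years, or
#'   year + composite period). Numeric labels must be strictly increasing.
#' @return An object of class `vd_stack`.
#' @export
vd_stack <- function(grids, time = seq_along(grids)) {
  if (length(grids) == 0L) stop("a vd_stack needs at least one grid")
  if (!all(vapply(grids, is_vd_grid, logical(1))))
    stop("all stack members must be vd_grid objects")
  if (length(time) != length(grids))
    stop("time labels and grids differ in length")
  ref <- grids[[1]]
  ok <- vapply(grids, same_geometry, logical(1), b = ref)
  if (!all(ok))
    stop("grids ", paste(which(!ok), collapse = ", "), " do not share the stack geometry")
  if (is.numeric(time) && any(diff(time) <= 0))
    stop("time index must be strictly increasing")
  structure(list(grids = grids, time = time), class = "vd_stack")
}

#' @export
print.vd_stack <- function(x, ...) {
  cat(sprintf("<vd_stack> %d layers, time %s .. %s\n", length(x$grids),
              x$time[1], x$time[length(x$time)]))
  print(x$grids[[1]])
  invisible(x)
}

#' @export
length.vd_stack <- function(x) length(x$grids)

is_vd_stack <- function(x) inherits(x, "vd_stack")

#' Flatten a stack to a layers-by-cells matrix
#'
#' Used by the vectorised per-pixel operations (trend, correlation). Cells
#' are taken in column-major matrix order.
#'
#' @param stack A [vd_stack()].
#' @return Numeric matrix, one row per layer, one column per cell.
#' @export
stack_matrix <- function(stack) {
  stopifnot(is_vd_stack(stack))
  t(vapply(stack$grids, function(g) as.vector(g$values),
           numeric(length(stack$grids[[1]]$values))))
}

#' Rebuild a grid from a per-cell vector on a template geometry
#'
#' @param template A [vd_grid()] supplying the geometry.
#' @param cells Numeric vector of `length(template$values)` in column-major
#'   order (as produced by [stack_matrix()] columns).
#' @return A [vd_grid()].
#' @export
grid_from_cells <- function(template, cells) {
  stopifnot(is_vd_grid(template), length(cells) == length(template$values))
  out <- template
  out$values <- matrix(as.double(cells), nrow = nrow(template$values))
  out
}
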