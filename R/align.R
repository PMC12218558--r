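#' Resample a grid onto the geometry of a reference grid
#'
#' Every pipeline statistic runs on one common geometry (that of the NDVI
#' stack); driver and factor grids are aligned to it with this function.
#' `nearest` assigns each reference cell the value of the source cell whose
#' centre is closest and never invents values absent from the source — it is
#' mandatory for categorical fields (land use, strata). `bilinear`
#' interpolates between the four surrounding source cell centres and is
#' conservative about missing data: if any contributing source cell is
#' masked, the output cell is masked, so no value is fabricated at lake or
#' nodata edges.
#'
#' Reference cells falling outside the source extent (outside the outermost
#' source cell centres, for `bilinear`) come out masked.
#'
#' @param grid Source [vd_grid()].
#' @param reference [vd_grid()] supplying the target geometry.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A [vd_grid()] on the reference geometry carrying the source CRS.
#' @examples
#' src <- vd_grid(matrix(1:4, 2, 2), dx = 2)
#' ref <- vd_grid(matrix(0, 4, 4), dx = 1)
#' align(src, ref, "nearest")$values   # each source value in a 2x2 block
#' @export
align <- function(grid, reference, method = c("bilinear", "nearest")) {
  stopifnot(is_vd_grid(grid), is_vd_grid(reference))
  method <- match.arg(method)
  es <- grid_extent(grid); er <- grid_extent(reference)
  if (es["xmax"] <= er["xmin"] || er["xmax"] <= es["xmin"] ||
      es["ymax"] <= er["ymin"] || er["ymax"] <= es["ymin"])
    stop(sprintf(
      "extents do not overlap: source x[%g,%g] y[%g,%g] vs reference x[%g,%g] y[%g,%g]",
      es["xmin"], es["xmax"], es["ymin"], es["ymax"],
      er["xmin"], er["xmax"], er["ymin"], er["ymax"]))
  rc <- grid_coords(reference)
  nr <- length(rc$y); nc <- length(rc$x)
  # fractional source indices of the reference cell centres
  gx <- (rc$x - grid$xmin) / grid$dx + 0.5          # 1-based column coord
  gy <- (grid$ymin + nrow(grid$values) * grid$dy - rc$y) / grid$dy + 0.5
  out <- matrix(NA_real_, nr, nc)
  sv <- grid$values
  snr <- nrow(sv); snc <- ncol(sv)
  if (method == "nearest") {
    j <- round(gx); i <- round(gy)
    okj <- j >= 1 & j <= snc; oki <- i >= 1 & i <= snr
    ii <- rep(i, times = nc); jj <- rep(j, each = nr)
    ok <- rep(oki, times = nc) & rep(okj, each = nr)
    idx <- (jj - 1L) * snr + ii
    out[ok] <- sv[idx[ok]]
  } else {
    j0 <- pmin(pmax(floor(gx), 1L), max(snc - 1L, 1L))
    i0 <- pmin(pmax(floor(gy), 1L), max(snr - 1L, 1L))
    fx <- gx - j0; fy <- gy - i0
    okj <- gx >= 1 & gx <= snc; oki <- gy >= 1 & gy <= snr
    J0 <- rep(j0, each = nr); I0 <- rep(i0, times = nc)
    FX <- rep(fx, each = nr); FY <- rep(fy, times = nc)
    ok <- rep(oki, times = nc) & rep(okj, each = nr)
    at <- function(i, j) sv[(j - 1L) * snr + i]
    J1 <- pmin(J0 + 1L, snc); I1 <- pmin(I0 + 1L, snr)  # single-row/col sources
    v00 <- at(I0, J0); v01 <- at(I0, J1)
    v10 <- at(I1, J0); v11 <- at(I1, J1)
    val <- (1 - FY) * ((1 - FX) * v00 + FX * v01) +
           FY * ((1 - FX) * v10 + FX * v11)
    out[ok] <- val[ok]  # NA contributors propagate through the arithmetic
  }
  vd_grid(out, xmin = reference$xmin, ymin = reference$ymin,
          dx = reference$dx, dy = reference$dy, crs = grid$crs)
}

#' Align every layer of a stack to a reference geometry
#'
#' @param stack A [vd_stack()].
#' @inheritParams align
#' @return A [vd_stack()] on the reference geometry.
#' @export
align_stack <- function(stack, reference, method = c("bilinear", "nearest")) {
  stopifnot(is_vd_stack(stack))
  method <- match.arg(method)
  vd_stack(lapply(stack$grids, align, reference = reference, method = method),
           time = stack$time)
}
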