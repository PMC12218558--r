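test_that("write/read roundtrip preserves values, mask, georeference and CRS", {
  v <- matrix(runif(20), 4, 5)
  v[2, 3] <- NA
  g <- vd_grid(v, xmin = 95.9, ymin = 32.2, dx = 0.083, crs = "EPSG:4326")
  path <- file.path(withr::local_tempdir(), "g.asc")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_identical(is.na(g2$values), is.na(g$values))
  expect_equal(g2$xmin, g$xmin)
  expect_equal(g2$ymin, g$ymin)
  expect_equal(g2$dx, g$dx)
  expect_identical(g2$crs, "EPSG:4326")
})

test_that("nodata semantics: constant and fully masked grids survive roundtrip", {
  d <- withr::local_tempdir()
  half <- vd_grid(matrix(0.5, 3, 3))
  write_grid(half, file.path(d, "half.asc"))
  expect_true(all(read_grid(file.path(d, "half.asc"))$values == 0.5))

  masked <- vd_grid(matrix(NA_real_, 3, 3))
  write_grid(masked, file.path(d, "masked.asc"))
  expect_true(all(is.na(read_grid(file.path(d, "masked.asc"))$values)))
})

test_that("unreadable files and missing georeference are explicit errors", {
  expect_error(read_grid("no/such/file.asc"), "no such file")
  bad <- file.path(withr::local_tempdir(), "bad.asc")
  writeLines(c("ncols 2", "nrows 2", "1 2", "3 4", "5 6"), bad)
  expect_error(read_grid(bad), "georeference")
})

test_that("multi-layer stacks roundtrip with layer indexing intact", {
  d <- withr::local_tempdir()
  grids <- lapply(1:3, function(i) vd_grid(matrix(i * 1.0, 2, 2)))
  st <- vd_stack(grids, time = c(2001, 2002, 2003))
  write_stack(st, d, "ndvi")
  st2 <- read_stack(d, "ndvi")
  expect_equal(length(st2), 3L)
  expect_equal(st2$grids[[2]]$values, grids[[2]]$values)  # second layer is second field
  expect_equal(st2$time, c(2001, 2002, 2003))
  expect_error(read_grid(file.path(d, "ndvi_2001.asc"), band = 2), "single-band")
})

test_that("stack construction enforces shared geometry and increasing time", {
  a <- vd_grid(matrix(0, 2, 2)); b <- vd_grid(matrix(0, 3, 2))
  expect_error(vd_stack(list(a, b)), "geometry")
  expect_error(vd_stack(list(a, a), time = c(2, 1)), "increasing")
})

test_that("align: identity, nearest block upsampling, bilinear midpoint", {
  src <- vd_grid(matrix(c(1, 3, 2, 4), 2, 2), dx = 2)   # 2x2, cells of size 2
  expect_equal(align(src, src, "nearest")$values, src$values)

  ref <- vd_grid(matrix(0, 4, 4), dx = 1)
  up <- align(src, ref, "nearest")$values
  expect_equal(up, matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))

  # midpoint between cell centres holding 0 and 1 interpolates to 0.5
  line <- vd_grid(matrix(c(0, 1), 1, 2), dx = 1)
  mid <- vd_grid(matrix(0, 1, 1), xmin = 0.5, ymin = 0, dx = 1)
  expect_equal(align(line, mid, "bilinear")$values[1, 1], 0.5)
})

test_that("bilinear masks any output with a masked contributor; nearest invents nothing", {
  v <- matrix(as.double(1:16), 4, 4); v[2, 2] <- NA
  src <- vd_grid(v, dx = 1)
  ref <- vd_grid(matrix(0, 8, 8), dx = 0.5)
  bl <- align(src, ref, "bilinear")
  # the four reference cells straddling the masked source cell centre are NA
  expect_true(anyNA(bl$values))
  nn <- align(src, ref, "nearest")
  got <- nn$values[!is.na(nn$values)]
  expect_true(all(got %in% v[!is.na(v)]))
})

test_that("align is idempotent on an already-aligned grid and rejects disjoint extents", {
  g <- vd_grid(matrix(runif(12), 3, 4), xmin = 10, ymin = 20, dx = 0.5)
  ref <- vd_grid(matrix(0, 3, 4), xmin = 10, ymin = 20, dx = 0.5)
  once <- align(g, ref, "bilinear")
  twice <- align(once, ref, "bilinear")
  expect_equal(twice$values, once$values)

  far <- vd_grid(matrix(0, 3, 4), xmin = 1000, ymin = 2000, dx = 0.5)
  expect_error(align(g, far), "do not overlap")
})
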