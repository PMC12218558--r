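test_that("pixel slope: closed-form cases and lm() oracle", {
  expect_equal(pixel_slope(rep(0.5, 10)), 0)
  expect_equal(pixel_slope(as.double(1:8)), 1)
  expect_equal(pixel_slope(c(0.2, 0.4, 0.3)), 0.05)

  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    y <- rnorm(n)
    fit <- lm(y ~ seq_len(n))
    expect_equal(pixel_slope(y), unname(coef(fit)[2]), tolerance = 1e-12)
  }
})

test_that("pixel slope is vectorised and honours the minimum-years rule", {
  m <- cbind(a = as.double(1:6), b = rep(2, 6), c = c(1, 2, NA, NA, NA, NA))
  sl <- pixel_slope(m)
  expect_equal(unname(sl[1:2]), c(1, 0))
  expect_true(is.na(sl[3]))            # only 2 valid years
  # gappy series still matches lm on the valid subset
  y <- c(0.1, NA, 0.5, 0.4, NA, 0.9)
  ok <- !is.na(y)
  expect_equal(pixel_slope(y), unname(coef(lm(y[ok] ~ seq_along(y)[ok]))[2]),
               tolerance = 1e-12)
})

test_that("trend classes reproduce the printed boundary examples", {
  expect_equal(as.character(classify_trend(-0.002)), "obvious degradation")
  expect_equal(as.character(classify_trend(0)), "slight improvement")
  expect_equal(as.character(classify_trend(0.0006)), "significant improvement")
  expect_equal(as.character(classify_trend(-0.0019)), "obvious degradation")
  expect_equal(as.character(classify_trend(-0.0015)), "mild degradation")
  expect_equal(as.character(classify_trend(-0.0005)), "basically stable")
  expect_error(classify_trend(Inf), "non-finite")
})

test_that("trend classes partition the line; coverage classes partition (-0.3, 1]", {
  set.seed(31)
  theta <- c(runif(1e5, -0.01, 0.01), -0.0019, -0.001, -0.0002, 0.0006)
  cls <- classify_trend(theta)
  expect_false(anyNA(cls))                         # exactly one class each

  ndvi <- c(runif(1e5, -0.3 + 1e-9, 1), c(0, 0.2, 0.4, 0.6, 0.8, 1))
  cov <- classify_coverage(ndvi)
  expect_false(anyNA(cov))
  # right-closed: each printed boundary belongs to the left interval
  expect_equal(as.character(classify_coverage(c(0, 0.2, 0.4, 0.6, 0.8, 1))),
               c("bare", "low", "medium-low", "medium", "medium-high", "high"))
  expect_equal(as.character(classify_coverage(0.85)), "high")
  expect_error(classify_coverage(-0.31), "cannot be classified")
  expect_error(classify_coverage(1.1), "cannot be classified")
})

test_that("class proportions cover absent classes and sum to one", {
  f <- factor(c("low", "low", "medium", "high"),
              levels = c("bare", "low", "medium-low", "medium", "medium-high", "high"))
  p <- class_proportions(f)
  expect_equal(unname(p[c("low", "medium", "high")]), c(0.5, 0.25, 0.25),
               ignore_attr = TRUE)
  expect_equal(unname(p["bare"]), 0, ignore_attr = TRUE)
  expect_equal(sum(p), 1)

  g <- class_map(vd_grid(matrix(runif(100, 0, 1 - 1e-9), 10, 10)), "coverage")
  expect_equal(sum(class_proportions(g)), 1, tolerance = 1e-9)
  one <- class_map(vd_grid(matrix(0.5, 3, 3)), "coverage")
  expect_equal(unname(class_proportions(one)["medium"]), 1, ignore_attr = TRUE)
  expect_error(class_proportions(factor(c(NA, NA))), "all cells masked")
})

test_that("proportion trends use percent per year and match a direct OLS oracle", {
  frac <- cbind(lowish = rep(0.25, 5), rising = seq(0.10, 0.14, by = 0.01))
  tr <- proportion_trend(frac)
  expect_equal(unname(tr["lowish"]), 0)
  expect_equal(unname(tr["rising"]), 1)            # +1 percentage point / year
  set.seed(8)
  f2 <- cbind(r = runif(7))
  expect_equal(unname(proportion_trend(f2)["r"]),
               unname(coef(lm(f2[, 1] * 100 ~ seq_len(7)))[2]), tolerance = 1e-12)
})

test_that("slope map reproduces designed per-cell trends", {
  template <- vd_grid(matrix(0, 4, 4))
  slopes <- matrix(seq(-0.003, 0.003, length.out = 16), 4, 4)
  grids <- lapply(1:10, function(t) grid_from_cells(template, 0.5 + slopes * t))
  sm <- slope_map(vd_stack(grids, time = 2000 + 1:10))
  expect_equal(sm$values, slopes, tolerance = 1e-12)
})
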