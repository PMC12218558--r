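test_that("segment deviations match direct evaluation", {
  expect_equal(unname(segment_deviations(make_toy_series("step"), 3)), c(0, 0, 0))
  expect_equal(unname(segment_deviations(make_toy_series("ramp"), 3)), c(2, 2, 4))
  const <- make_toy_series("constant", 5, params = 0.63)
  for (tau in 1:4)
    expect_equal(unname(segment_deviations(const, tau)), c(0, 0, 0))
  expect_error(segment_deviations(make_toy_series("ramp"), 6), "tau must lie")
})

test_that("oca locates the optimal split and flags degenerate series", {
  fit <- oca(make_toy_series("step"))          # (0,0,0,10,10,10)
  expect_equal(fit$tau_star, 3L)
  expect_equal(min(fit$sn_curve$Sn), 0)
  expect_equal(fit$split_year, 2003L)

  ramp <- oca(make_toy_series("ramp"))
  expect_equal(ramp$tau_star, 3L)
  expect_equal(min(ramp$sn_curve$Sn), 4)

  const <- oca(make_toy_series("constant", 8, params = 0.5))
  expect_true(const$no_change_point)
})

test_that("oca equals the brute-force scan on random series (property)", {
  set.seed(101)
  for (rep in 1:120) {
    n <- sample(5:50, 1)
    x <- rnorm(n) + cumsum(rnorm(n, 0, 0.3))
    fit <- oca(annual_series(2000 + seq_len(n) - 1, x))
    orc <- oracle_oca(x)
    expect_identical(fit$tau_star, orc$tau)
    expect_equal(min(fit$sn_curve$Sn), orc$sn_min, tolerance = 1e-12)
    # Sn is nonnegative and never exceeds the whole-series deviation sum
    expect_true(all(fit$sn_curve$Sn >= 0))
    expect_true(all(fit$sn_curve$Sn <= sum((x - mean(x))^2) + 1e-12))
  }
})

test_that("jump test: pooled-t value, degenerate variances, t.test cross-check", {
  jt <- jump_test(make_toy_series("step"), 3)
  expect_identical(jt$t_stat, Inf)
  expect_true(jt$significant)

  const <- jump_test(make_toy_series("constant", 6, params = 1), 3)
  expect_equal(const$t_stat, 0)
  expect_false(const$significant)

  s <- annual_series(2001:2006, c(1, 2, 3, 7, 8, 9))
  jt2 <- jump_test(s, 3)
  expect_equal(jt2$t_stat, 6 / sqrt(2 / 3), tolerance = 1e-12)  # hand evaluation
  tt <- t.test(c(1, 2, 3), c(7, 8, 9), var.equal = TRUE)        # independent route
  expect_equal(jt2$t_stat, abs(unname(tt$statistic)), tolerance = 1e-12)
})

test_that("jump statistic is invariant to shifting and scaling the series", {
  set.seed(5)
  x <- rnorm(12)
  s0 <- annual_series(1:12 + 2000, x)
  base <- jump_test(s0, 5)$t_stat
  expect_equal(jump_test(annual_series(1:12 + 2000, x + 100), 5)$t_stat, base)
  expect_equal(jump_test(annual_series(1:12 + 2000, x * 7), 5)$t_stat, base)
  expect_equal(jump_test(annual_series(1:12 + 2000, -3 * x + 2), 5)$t_stat, base)
})

test_that("critical values follow the printed convention", {
  expect_equal(round(critical_value(0.05), 2), 1.64)
  expect_equal(critical_value(0.5), 0)
  expect_equal(critical_value(0.01), 2.3263479, tolerance = 1e-6)  # frozen quantile
  expect_equal(round(critical_value(0.05, two_sided = TRUE), 2), 1.96)
  expect_error(critical_value(0), "between 0 and 1")
  expect_error(critical_value(1.2), "between 0 and 1")
})

test_that("segmentation splits inclusively and reassembles exactly", {
  s <- annual_series(1982:2020, seq(0.62, 0.68, length.out = 39))
  seg <- segment(s, 2009)
  expect_equal(nrow(seg$before), 28L)
  expect_equal(nrow(seg$after), 11L)
  expect_equal(rbind(as.data.frame(seg$before), as.data.frame(seg$after)),
               as.data.frame(s), ignore_attr = TRUE)
  expect_error(segment(s, 1982), "strictly inside")
  expect_error(segment(s, 2020), "strictly inside")
  # penultimate year leaves a single-year second segment (allowed here)
  expect_equal(nrow(segment(s, 2019)$after), 1L)
})

test_that("series construction rejects gaps and incomplete values", {
  expect_error(annual_series(c(2000, 2002), c(1, 2)), "gap-free")
  expect_error(annual_series(2000:2002, c(1, NA, 3)), "complete")
})
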