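test_that("jenks breaks: separated clusters, degenerate class counts", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), 10)
  expect_equal(jenks_breaks(c(5, 1, 3), 1), numeric(0))
  b <- jenks_breaks(c(4, 1, 9, 2), 4)        # every distinct value its own class
  expect_equal(jenks_sse(c(4, 1, 9, 2), b), 0)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("jenks equals the exhaustive contiguous-partition oracle (property)", {
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(5:14, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 3)
    if (length(unique(x)) < k) next
    b <- jenks_breaks(x, k)
    orc <- oracle_jenks(x, k)
    expect_equal(jenks_sse(x, b), orc$sse, tolerance = 1e-9)
    expect_equal(b, orc$breaks)
  }
})

test_that("stratify uses left-closed bins with equal-to-threshold in the upper stratum", {
  expect_equal(stratify(0.5, c(1, 2)), 1L)
  expect_equal(stratify(1, c(1, 2)), 2L)
  expect_equal(stratify(c(0, 1, 1.5, 2, 3), c(1, 2)), c(1L, 2L, 2L, 3L, 3L))
  set.seed(62)
  v <- runif(100, 0, 10); thr <- c(2.5, 5, 7.5)
  lab <- stratify(v, thr)
  direct <- 1L + (v >= 2.5) + (v >= 5) + (v >= 7.5)   # comparison oracle
  expect_identical(lab, as.integer(direct))
  expect_error(stratify(1, c(2, 1)), "sorted")
})

test_that("factor q: worked instance, degenerate strata, direct-summation oracle", {
  expect_equal(factor_q(c(1, 2, 3, 4), c("A", "A", "B", "B")), 0.8)
  expect_equal(factor_q(rnorm(10), rep("A", 10)), 0)          # single stratum
  expect_equal(factor_q(c(1, 1, 5, 5, 9, 9), c(1, 1, 2, 2, 3, 3)), 1)
  expect_error(factor_q(rep(2, 5), c(1, 1, 2, 2, 2)), "zero total variance")

  set.seed(63)
  for (rep in 1:100) {
    n <- sample(10:80, 1)
    y <- rnorm(n)
    s <- sample(letters[1:sample(2:6, 1)], n, replace = TRUE)
    if (length(unique(s)) < 2) next
    q <- factor_q(y, s)
    expect_true(q >= 0 && q <= 1)
    expect_equal(q, oracle_q(y, s), tolerance = 1e-12)
  }
})

test_that("q is invariant under affine transforms of the response", {
  set.seed(64)
  y <- rnorm(40); s <- sample(1:4, 40, replace = TRUE)
  q0 <- factor_q(y, s)
  expect_equal(factor_q(5 * y - 3, s), q0, tolerance = 1e-12)
  expect_equal(factor_q(-0.2 * y + 10, s), q0, tolerance = 1e-12)
})

test_that("interaction q reduces to the single factor for constant or identical partners", {
  set.seed(65)
  y <- rnorm(30); a <- sample(1:3, 30, replace = TRUE)
  qa <- factor_q(y, a)
  expect_equal(interaction_q(y, a, rep(1, 30)), qa, tolerance = 1e-12)
  expect_equal(interaction_q(y, a, a), qa, tolerance = 1e-12)
  # explicit overlay oracle
  b <- sample(1:2, 30, replace = TRUE)
  overlay <- paste(a, b)
  expect_equal(interaction_q(y, a, b), factor_q(y, overlay), tolerance = 1e-12)
})

test_that("overlay refinement never reduces q (property)", {
  set.seed(66)
  for (rep in 1:100) {
    n <- sample(20:100, 1)
    y <- rnorm(n)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    qab <- interaction_q(y, a, b)
    expect_gte(qab, max(factor_q(y, a), factor_q(y, b)) - 1e-12)
  }
})

test_that("interaction taxonomy follows the five printed categories in order", {
  expect_equal(classify_interaction(0.3, 0.4, 0.5), "double-factor enhancement")
  expect_equal(classify_interaction(0.3, 0.4, 0.8), "nonlinear enhancement")
  expect_equal(classify_interaction(0.3, 0.4, 0.2), "nonlinear weakening")
  expect_equal(classify_interaction(0.3, 0.4, 0.7), "independence")
  expect_equal(classify_interaction(0.3, 0.4, 0.35), "single-factor nonlinear weakening")
  expect_error(classify_interaction(0.3, 0.4, 1.2), "\\[0, 1\\]")
})

test_that("permutation significance: determinism, perfect separation, n_perm floor", {
  set.seed(67)
  s <- rep(1:4, each = 10)
  y <- make_stratified_response(s, 0.9, seed = 3)
  p1 <- q_significance(y, s, n_perm = 199, seed = 9)
  p2 <- q_significance(y, s, n_perm = 199, seed = 9)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 200)            # minimum attainable
  expect_error(q_significance(y, s, n_perm = 50), "at least 99")
})

test_that("noncentral-F reference agrees with permutation on a clear effect", {
  set.seed(68)
  s <- rep(1:4, each = 15)
  y <- make_stratified_response(s, 0.5, seed = 4)
  p_f <- q_significance(y, s, method = "noncentral_f")
  expect_lt(p_f, 0.05)
  y0 <- rnorm(60)
  expect_gt(q_significance(y0, s, method = "noncentral_f"), 0.001)
})

test_that("point sampling is reproducible, distinct, and reports drops", {
  g <- vd_grid(matrix(runif(400), 20, 20))
  fac <- list(f1 = vd_grid(matrix(runif(400), 20, 20)))
  t1 <- sample_points(g, fac, 50, seed = 7)
  t2 <- sample_points(g, fac, 50, seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 50)
  expect_equal(anyDuplicated(t1[c("x", "y")]), 0L)

  small <- vd_grid(matrix(runif(4), 2, 2))
  t3 <- sample_points(small, list(f = small), 4, seed = 1, min_points = 4)
  expect_equal(nrow(t3), 4)

  # drop fraction tracks the masked fraction (binomial 3 sigma)
  vm <- matrix(runif(1600), 40, 40); vm[sample(1600, 400)] <- NA
  gm <- vd_grid(vm)
  tm <- sample_points(gm, list(f = vd_grid(matrix(1, 40, 40))), 400, seed = 8)
  dropped <- attr(tm, "n_dropped")
  expect_true(abs(dropped - 100) <= 3 * sqrt(400 * 0.25 * 0.75))
  expect_error(sample_points(g, fac, 10), "n >= 30")
})

test_that("the full detector fit recovers designed q, symmetry, and sensible classes", {
  set.seed(69)
  n <- 1600
  sA <- sample(1:5, n, replace = TRUE)
  y <- make_stratified_response(sA, 0.76, seed = 11)
  tab <- data.frame(response = y,
                    A = sA + runif(n, 0, 0.49),  # continuous proxy re-binned by Jenks
                    B = rnorm(n))
  fit <- geodetector(tab, factors = c("A", "B"), k = 5, n_perm = 199, seed = 12)
  qA <- fit$factor_table$q[fit$factor_table$factor == "A"]
  expect_true(abs(qA - 0.76) < 0.05)
  expect_equal(fit$interaction_q, t(fit$interaction_q))
  expect_true(all(!is.na(fit$interaction_class[upper.tri(fit$interaction_class)])))
  expect_output(print(fit), "Factor detector")
})

test_that("identical factors interact under the epsilon rule as designed", {
  set.seed(70)
  s <- sample(1:3, 60, replace = TRUE)
  y <- make_stratified_response(s, 0.5, seed = 5)
  tab <- data.frame(response = y, A = factor(s), B = factor(s))
  fit <- geodetector(tab, factors = c("A", "B"), categorical = c("A", "B"),
                     n_perm = 99, seed = 6)
  # overlay of a factor with itself: qAB = qA = qB < qA + qB
  expect_equal(fit$interaction_q[1, 2], fit$factor_table$q[1], tolerance = 1e-12)
  expect_equal(fit$interaction_class[1, 2], "single-factor nonlinear weakening")
})
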