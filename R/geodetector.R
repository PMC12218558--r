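# Seed hygiene: run code under a given seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Jenks natural breaks (Fisher's optimal partition)
#'
#' Thresholds minimising the total within-class sum of squared deviations
#' over all contiguous partitions of the sorted values into `k` classes —
#' the exact dynamic-programming solution, not the iterative heuristic.
#' Tied values always stay in one class.
#'
#' @param values Numeric vector with at least `k` distinct finite values.
#' @param k Number of classes.
#' @return Numeric vector of `k - 1` thresholds, each the smallest value of
#'   its upper class, so that [stratify()] with left-closed binning
#'   reproduces the optimal partition. `k = 1` returns an empty vector.
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)  # 10
#' @export
jenks_breaks <- function(values, k) {
  v <- values[!is.na(values)]
  if (any(!is.finite(v))) stop("values must be finite")
  u <- sort(unique(v))
  m <- length(u)
  if (k < 1L) stop("k must be >= 1")
  if (m < k) stop("need at least k = ", k, " distinct values, have ", m)
  if (k == 1L) return(numeric(0))
  w <- as.numeric(table(factor(v, levels = u)))    # tie counts
  cw <- c(0, cumsum(w))
  cs <- c(0, cumsum(w * u))
  cs2 <- c(0, cumsum(w * u^2))
  sse <- function(a, b) {   # weighted SSE of unique values a..b
    W <- cw[b + 1L] - cw[a]
    S <- cs[b + 1L] - cs[a]
    (cs2[b + 1L] - cs2[a]) - S^2 / W
  }
  # D[j, i]: minimal SSE of the first i unique values in j classes
  D <- matrix(Inf, k, m)
  B <- matrix(0L, k, m)     # first index of the last class
  for (i in seq_len(m)) { D[1L, i] <- sse(1L, i); B[1L, i] <- 1L }
  for (j in 2:k) {
    for (i in j:m) {
      starts <- j:i
      cand <- D[j - 1L, starts - 1L] +
        vapply(starts, function(a) sse(a, i), numeric(1))
      best <- which.min(cand)
      D[j, i] <- cand[best]
      B[j, i] <- starts[best]
    }
  }
  breaks <- numeric(k - 1L)
  i <- m
  for (j in k:2) {
    a <- B[j, i]
    breaks[j - 1L] <- u[a]
    i <- a - 1L
  }
  breaks
}

#' Assign stratum labels from thresholds
#'
#' Left-closed binning: a value equal to a threshold belongs to the upper
#' stratum, i.e. label `= 1 + #\{thresholds <= value\}`.
#'
#' @param values Numeric vector.
#' @param thresholds Sorted numeric thresholds (possibly empty).
#' @return Integer labels in `1..(length(thresholds) + 1)`.
#' @export
stratify <- function(values, thresholds) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  out <- rep(1L, length(values))
  for (t in thresholds) out <- out + (values >= t)
  out[is.na(values)] <- NA_integer_
  as.integer(out)
}

#' Factor-detector q-statistic
#'
#' The fraction of the response's variance explained by a stratification,
#' \deqn{q = 1 - \frac{\sum_h N_h \delta_h^2}{N \delta^2} = 1 - \mathrm{SSW}/\mathrm{SST},}
#' with population (divide-by-count) variances in both numerator and
#' denominator — any consistent convention cancels; mixing conventions is
#' the classic implementation bug and is foreclosed here by working with
#' sums of squares directly.
#'
#' @param y Numeric response, no `NA`.
#' @param strata Stratum labels (any vector coercible to factor), no `NA`.
#' @return q in \[0, 1\].
#' @export
factor_q <- function(y, strata) {
  if (anyNA(y) || anyNA(strata)) stop("y and strata must be complete")
  if (length(y) != length(strata)) stop("y and strata differ in length")
  if (length(y) < 2L) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("q undefined: zero total variance in y")
  f <- factor(strata)
  gm <- tapply(y, f, mean)
  ssw <- sum((y - gm[f])^2)
  q <- 1 - ssw / sst
  min(max(q, 0), 1)
}

#' Significance of a q-statistic
#'
#' The default is a seeded permutation test: strata labels are randomly
#' reassigned `n_perm` times and
#' \eqn{p = (1 + \#\{q_{perm} \ge q_{obs}\}) / (1 + n_{perm})}. The
#' `noncentral_f` method uses the reference distribution published for the
#' factor detector: \eqn{F = \frac{N - L}{L - 1}\frac{q}{1 - q}} against a
#' noncentral F with `L - 1` and `N - L` degrees of freedom.
#'
#' @inheritParams factor_q
#' @param method `"permutation"` (default) or `"noncentral_f"`.
#' @param n_perm Number of permutations (at least 99).
#' @param seed Integer seed for the permutation draw.
#' @return p-value.
#' @export
q_significance <- function(y, strata, method = c("permutation", "noncentral_f"),
                           n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  q_obs <- factor_q(y, strata)
  f <- factor(strata)
  N <- length(y); L <- nlevels(f)
  if (method == "noncentral_f") {
    if (L >= N) stop("noncentral F undefined: as many strata as points")
    if (q_obs >= 1) return(0)
    Fv <- (N - L) / (L - 1) * q_obs / (1 - q_obs)
    Nh <- as.numeric(table(f))
    mh <- tapply(y, f, mean)
    sigma2 <- sum((y - mean(y))^2) / N
    lambda <- (sum(mh^2) - (sum(sqrt(Nh) * mh))^2 / N) / sigma2
    return(stats::pf(Fv, L - 1, N - L, ncp = lambda, lower.tail = FALSE))
  }
  if (n_perm < 99L) stop("n_perm must be at least 99")
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      qb <- factor_q(y, f[sample.int(N)])
      if (qb >= q_obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + n_perm)
  })
}

#' Interaction-detector q of two stratifications
#'
#' q of the overlay partition: each occupied pair of strata `(h_A, h_B)`
#' becomes one overlay stratum (empty pairs drop out). On the same sample
#' the overlay refines both inputs, so the within-class sum of squares
#' cannot increase and `interaction_q >= max(q_A, q_B)` structurally —
#' which is why "enhancement" is the generic empirical outcome.
#'
#' @inheritParams factor_q
#' @param strataA,strataB Stratum labels of the two factors.
#' @return q of the overlay.
#' @export
interaction_q <- function(y, strataA, strataB) {
  overlay <- interaction(factor(strataA), factor(strataB), drop = TRUE)
  factor_q(y, overlay)
}

.interaction_categories <- c("nonlinear weakening", "single-factor nonlinear weakening",
                             "double-factor enhancement", "independence",
                             "nonlinear enhancement")

#' Categorise a pairwise interaction
#'
#' The five-way taxonomy comparing the overlay q (`qAB`) with the
#' single-factor values: independence (`qAB = qA + qB` within `epsilon`),
#' nonlinear enhancement (`qAB > qA + qB`), double-factor enhancement
#' (`qAB > max`), nonlinear weakening (`qAB < min`), and single-factor
#' nonlinear weakening otherwise.
#'
#' @param qA,qB,qAB Single-factor and overlay q values, all in \[0, 1\].
#' @param epsilon Tolerance for the independence category (q scale).
#' @return Category label.
#' @export
classify_interaction <- function(qA, qB, qAB, epsilon = 1e-6) {
  v <- c(qA, qB, qAB)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("q values must lie in [0, 1]")
  if (abs(qAB - (qA + qB)) <= epsilon) return("independence")
  if (qAB > qA + qB) return("nonlinear enhancement")
  if (qAB > max(qA, qB)) return("double-factor enhancement")
  if (qAB < min(qA, qB)) return("nonlinear weakening")
  "single-factor nonlinear weakening"
}

#' Random point sample of co-registered grids
#'
#' Draws `n` distinct cells uniformly at random (seeded, reproducible) and
#' extracts the response and every factor at their centres. Points carrying
#' a masked value in any layer are dropped and counted — the package's
#' operational definition of "outliers removed".
#'
#' @param response A [vd_grid()] with the response (e.g. period-mean NDVI).
#' @param factors Named list of [vd_grid()] objects on the same geometry.
#' @param n Points to draw.
#' @param seed Integer seed.
#' @param min_points Floor on both the requested and the surviving point
#'   count (default 30, the usual minimum for a stable q); lower it only for
#'   toy grids.
#' @return A data frame of class `sample_table` with columns `id`, `x`, `y`,
#'   `response`, then one column per factor; attribute `n_dropped` records
#'   the masked-point count.
#' @export
sample_points <- function(response, factors, n, seed = 1L, min_points = 30L) {
  stopifnot(is_vd_grid(response), is.list(factors), length(factors) > 0L)
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop("factors must be a named list")
  for (nm in names(factors)) {
    if (!is_vd_grid(factors[[nm]])) stop("factor '", nm, "' is not a vd_grid")
    if (!same_geometry(response, factors[[nm]]))
      stop("factor '", nm, "' is not co-registered with the response")
  }
  if (n < min_points) stop("need n >= ", min_points, " sample points")
  ncell <- length(response$values)
  if (n > ncell) stop("more points requested than cells available")
  cells <- with_seed(seed, sample.int(ncell, n))
  cc <- grid_coords(response)
  nr <- nrow(response$values)
  i <- (cells - 1L) %% nr + 1L
  j <- (cells - 1L) %/% nr + 1L
  tab <- data.frame(id = seq_len(n), x = cc$x[j], y = cc$y[i],
                    response = response$values[cells])
  for (nm in names(factors)) tab[[nm]] <- factors[[nm]]$values[cells]
  keep <- stats::complete.cases(tab)
  dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) < min_points)
    stop("fewer than ", min_points, " points remain after dropping ",
         dropped, " masked points")
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, n_dropped = dropped, class = c("sample_table", "data.frame"))
}

#' Fit the geographical detector to a sample table
#'
#' Discretises every continuous factor with [jenks_breaks()] (categorical
#' factors pass through unchanged), computes the factor-detector q and its
#' significance for each factor, and the full pairwise interaction-detector
#' matrix with the five-way category labels.
#'
#' @param table A `sample_table` from [sample_points()], or any data frame
#'   holding the response and factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names; defaults to every
#'   column except `response`, `id`, `x`, `y`.
#' @param k Jenks class count per continuous factor (recycled, or a named
#'   vector).
#' @param categorical Names of factors to treat as categorical (e.g. land
#'   use, aspect sector) — no discretization.
#' @param sig_method,n_perm,seed Passed to [q_significance()].
#' @param epsilon Independence tolerance, see [classify_interaction()].
#' @return An object of class `geodetector`: `factor_table` (data frame with
#'   `factor`, `q`, `p`, `stars`, `L`), `interaction_q` and
#'   `interaction_class` matrices, `strata` (the labels used), `n_used`.
#' @examples
#' d <- data.frame(response = c(1, 2, 3, 4), f = c("A", "A", "B", "B"))
#' fit <- geodetector(d, factors = "f", categorical = "f", n_perm = 99)
#' fit$factor_table$q   # 0.8
#' @export
geodetector <- function(table, response = "response", factors = NULL,
                        k = 5L, categorical = character(0),
                        sig_method = c("permutation", "noncentral_f"),
                        n_perm = 999L, seed = 1L, epsilon = 1e-6) {
  sig_method <- match.arg(sig_method)
  tab <- as.data.frame(table)
  if (!response %in% names(tab)) stop("no response column '", response, "'")
  if (is.null(factors))
    factors <- setdiff(names(tab), c(response, "id", "x", "y"))
  if (length(factors) < 1L) stop("no factor columns")
  miss <- setdiff(factors, names(tab))
  if (length(miss) > 0) stop("missing factor columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(tab[c(response, factors)])
  tab <- tab[keep, , drop = FALSE]
  y <- tab[[response]]
  if (length(k) == 1L) k <- stats::setNames(rep(k, length(factors)), factors)
  strata <- list()
  breaks <- list()
  for (f in factors) {
    if (f %in% categorical) {
      strata[[f]] <- factor(tab[[f]])
      breaks[[f]] <- NULL
    } else {
      kb <- min(as.integer(k[[f]]), length(unique(tab[[f]])))
      br <- jenks_breaks(tab[[f]], kb)
      breaks[[f]] <- br
      strata[[f]] <- factor(stratify(tab[[f]], br))
    }
    if (nlevels(strata[[f]]) < 2L)
      stop("factor '", f, "' has fewer than 2 occupied strata")
  }
  qv <- vapply(factors, function(f) factor_q(y, strata[[f]]), numeric(1))
  pv <- vapply(seq_along(factors), function(i)
    q_significance(y, strata[[factors[i]]], method = sig_method,
                   n_perm = n_perm, seed = seed + i), numeric(1))
  stars <- ifelse(pv < 0.01, "***", ifelse(pv < 0.05, "**",
           ifelse(pv < 0.1, "*", "")))
  nf <- length(factors)
  iq <- matrix(NA_real_, nf, nf, dimnames = list(factors, factors))
  icl <- matrix(NA_character_, nf, nf, dimnames = list(factors, factors))
  diag(iq) <- qv
  for (a in seq_len(nf)) for (b in seq_len(nf)) if (a < b) {
    qab <- interaction_q(y, strata[[factors[a]]], strata[[factors[b]]])
    iq[a, b] <- iq[b, a] <- qab
    cl <- classify_interaction(qv[a], qv[b], qab, epsilon = epsilon)
    icl[a, b] <- icl[b, a] <- cl
  }
  structure(list(
    factor_table = data.frame(
      factor = factors, q = unname(qv), p = pv, stars = stars,
      L = vapply(strata, nlevels, integer(1))[factors],
      row.names = NULL),
    interaction_q = iq,
    interaction_class = icl,
    strata = strata,
    breaks = breaks,
    n_used = length(y),
    n_dropped = sum(!keep) + (attr(table, "n_dropped") %||% 0L),
    sig_method = sig_method
  ), class = "geodetector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.geodetector <- function(x, ...) {
  cat(sprintf("Geographical detector fit (%d points, %s test)\n",
              x$n_used, x$sig_method))
  ft <- x$factor_table[order(-x$factor_table$q), ]
  cat("\nFactor detector (q, descending):\n")
  for (i in seq_len(nrow(ft)))
    cat(sprintf("  %-16s q = %5.3f %-3s (p = %.3g, L = %d)\n",
                ft$factor[i], ft$q[i], ft$stars[i], ft$p[i], ft$L[i]))
  cat("\nInteraction detector: ")
  cls <- x$interaction_class[upper.tri(x$interaction_class)]
  tb <- sort(table(cls), decreasing = TRUE)
  cat(paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.geodetector <- function(object, ...) {
  print(object)
  cat("\nInteraction q matrix:\n")
  print(round(object$interaction_q, 3))
  invisible(object)
}

#' @export
plot.geodetector <- function(x, ...) {
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  ft <- x$factor_table[order(-x$factor_table$q), ]
  bp <- graphics::barplot(ft$q, names.arg = paste0(ft$factor, ft$stars),
                          las = 2, ylab = "q", ylim = c(0, 1),
                          main = "factor detector", ...)
  invisible(x)
}
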