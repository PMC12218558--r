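# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Brute-force ordered-cluster scan: direct evaluation of the two-segment
# sums of squared deviations at every admissible split.
oracle_oca <- function(x) {
  n <- length(x)
  taus <- 2:(n - 2)
  sn <- vapply(taus, function(tt) {
    a <- x[1:tt]; b <- x[(tt + 1):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  list(tau = taus[which.min(sn)], sn_min = min(sn), sn = sn)
}

# q by direct summation: population SSW / SST, written with explicit loops.
oracle_q <- function(y, strata) {
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (s in unique(strata)) {
    ys <- y[strata == s]
    ssw <- ssw + sum((ys - mean(ys))^2)
  }
  1 - ssw / sst
}

# Exhaustive contiguous-partition search for the optimal k-class split of
# sorted values: enumerates every choice of k-1 cut gaps.
oracle_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(list(sse = sse(x), breaks = numeric(0)))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_breaks <- NULL
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, ci], n)
    tot <- 0
    for (j in seq_len(k)) tot <- tot + sse(x[(bounds[j] + 1):bounds[j + 1]])
    if (tot < best) {
      best <- tot
      best_breaks <- x[cuts[, ci] + 1]   # first value of each upper class
    }
  }
  list(sse = best, breaks = best_breaks)
}

# Total within-class SSE achieved by a set of stratify()-style thresholds.
jenks_sse <- function(values, breaks) {
  lab <- vegdyn::stratify(values, breaks)
  tot <- 0
  for (s in unique(lab)) {
    v <- values[lab == s]
    tot <- tot + sum((v - mean(v))^2)
  }
  tot
}

# Small grid builders.
tiny_grid <- function(values, nrow = 2, ncol = 2, ...) {
  vd_grid(matrix(values, nrow, ncol), ...)
}
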