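#' Annual regional series
#'
#' The ordered series \eqn{x_1, \dots, x_n} (one value per year) on which
#' change-point detection operates. Years must be strictly increasing and
#' gap-free, and values complete: the ordered-cluster scan has no missing
#' data semantics, so gaps are rejected at construction.
#'
#' @param years Integer years, strictly increasing, consecutive.
#' @param values Numeric values, one per year, no `NA`.
#' @return A data frame of class `annual_series` with columns `year`,
#'   `value`.
#' @export
annual_series <- function(years, values) {
  years <- as.integer(years)
  if (length(years) != length(values)) stop("years and values differ in length")
  if (anyNA(years) || anyNA(values)) stop("annual series must be complete (no NA)")
  if (any(diff(years) != 1L))
    stop("years must be strictly increasing and gap-free")
  structure(data.frame(year = years, value = as.double(values)),
            class = c("annual_series", "data.frame"))
}

as_annual_series <- function(x) {
  if (inherits(x, "annual_series")) return(x)
  if (is.data.frame(x) && all(c("year", "value") %in% names(x)))
    return(annual_series(x$year, x$value))
  stop("cannot interpret input as an annual series")
}

#' Within-segment sums of squared deviations at a candidate split
#'
#' For a split after position `tau`, returns the within-segment sums of
#' squared deviations \eqn{V_\tau = \sum_{t \le \tau} (x_t - \bar x_\tau)^2}
#' and \eqn{V_{n-\tau} = \sum_{t > \tau} (x_t - \bar x_{n-\tau})^2}, and the
#' total \eqn{S_n(\tau) = V_\tau + V_{n-\tau}} that the ordered-cluster scan
#' minimises.
#'
#' @param series An [annual_series()] (or data frame with `year`, `value`).
#' @param tau Split position, `1 <= tau <= n - 1` (both segments nonempty).
#' @return Named numeric vector `c(V_before, V_after, S_n)`.
#' @export
segment_deviations <- function(series, tau) {
  s <- as_annual_series(series)
  n <- nrow(s)
  if (tau < 1L || tau > n - 1L)
    stop("tau must lie in 1..", n - 1L, ", got ", tau)
  x1 <- s$value[seq_len(tau)]
  x2 <- s$value[(tau + 1L):n]
  v1 <- sum((x1 - mean(x1))^2)
  v2 <- sum((x2 - mean(x2))^2)
  c(V_before = v1, V_after = v2, S_n = v1 + v2)
}

#' Normal-quantile critical value for the mean-jump test
#'
#' The default convention reproduces the threshold commonly printed for this
#' test at \eqn{\alpha = 0.05}, the standard normal quantile at
#' \eqn{1 - \alpha} (1.64 to two decimals). The strict two-sided variant
#' (quantile at \eqn{1 - \alpha/2}; 1.96 at 0.05) is available via
#' `two_sided = TRUE`.
#'
#' @param alpha Significance level in (0, 1).
#' @param two_sided Use the two-sided quantile.
#' @return Scalar critical value.
#' @export
critical_value <- function(alpha = 0.05, two_sided = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
}

#' Pooled-t test for a mean jump at a split
#'
#' Tests whether the segment means before and after the split differ, with
#' the pooled two-sample t statistic
#' \deqn{|T| = \frac{|\bar x_\tau - \bar x_{n-\tau}|}{s_p \sqrt{1/\tau + 1/(n-\tau)}},}
#' where \eqn{s_p} is the pooled within-segment standard deviation. A zero
#' pooled variance with unequal means gives \eqn{|T| = \infty} (significant);
#' with equal means, \eqn{|T| = 0}.
#'
#' @inheritParams segment_deviations
#' @param alpha Significance level.
#' @param two_sided Critical-value convention, see [critical_value()].
#' @return Named list: `t_stat` (|T|), `critical`, `significant`.
#' @export
jump_test <- function(series, tau, alpha = 0.05, two_sided = FALSE) {
  s <- as_annual_series(series)
  n <- nrow(s)
  if (tau < 2L || tau > n - 2L)
    stop("both segments need >= 2 points: tau must lie in 2..", n - 2L)
  x1 <- s$value[seq_len(tau)]
  x2 <- s$value[(tau + 1L):n]
  m1 <- mean(x1); m2 <- mean(x2)
  sp2 <- (sum((x1 - m1)^2) + sum((x2 - m2)^2)) / (n - 2L)
  crit <- critical_value(alpha, two_sided)
  tstat <- if (sp2 == 0) {
    if (m1 == m2) 0 else Inf
  } else {
    abs(m1 - m2) / sqrt(sp2 * (1 / tau + 1 / (n - tau)))
  }
  list(t_stat = tstat, critical = crit, significant = tstat > crit)
}

#' Ordered cluster analysis of an annual series
#'
#' Scans every admissible split \eqn{\tau} of the series, computing the total
#' within-segment sum of squared deviations \eqn{S_n(\tau)}; the minimising
#' \eqn{\tau^*} is the change point (mutation point). The scan range is
#' \eqn{2 \le \tau \le n - 2} so both segments always have at least two
#' points and the mean-jump test is defined at the optimum. Ties at the
#' minimum resolve to the earliest \eqn{\tau} and are recorded. Interior
#' local minima of the curve close to the global minimum are reported as
#' secondary minima: a multi-valley curve is the classic signature of more
#' than two regimes.
#'
#' @param series An [annual_series()] (or data frame with `year`, `value`,
#'   or a numeric vector — years then default to `1..n`).
#' @param alpha Significance level of the mean-jump test at the optimum.
#' @param two_sided Critical-value convention, see [critical_value()].
#' @param prominence Secondary-minimum threshold: an interior local minimum
#'   qualifies when its \eqn{S_n} exceeds \eqn{S_n(\tau^*)} by at most this
#'   fraction of \eqn{S_n(\tau^*)} (purely diagnostic).
#' @return An object of class `oca`: the full `sn_curve` (data frame
#'   `tau`, `year`, `Sn`), `tau_star`, `split_year` (last year of segment 1),
#'   segment means and deviations, the jump statistic with its critical
#'   value and significance flag, tie and no-change-point diagnostics, and
#'   `secondary_minima`.
#' @examples
#' fit <- oca(annual_series(2001:2010, c(rnorm(5), rnorm(5, 2))))
#' fit
#' summary(fit)
#' @export
oca <- function(series, alpha = 0.05, two_sided = FALSE, prominence = 0.10) {
  if (is.numeric(series) && is.null(dim(series)))
    series <- annual_series(seq_along(series), series)
  s <- as_annual_series(series)
  n <- nrow(s)
  if (n < 4L) stop("ordered cluster analysis needs at least 4 years")
  taus <- 2:(n - 2L)
  dev <- vapply(taus, function(tt) segment_deviations(s, tt), numeric(3))
  sn <- dev["S_n", ]
  no_change <- diff(range(sn)) <= .Machine$double.eps * max(1, max(sn))
  i_star <- which.min(sn)
  ties <- taus[abs(sn - sn[i_star]) <= .Machine$double.eps * max(1, sn[i_star])]
  tau_star <- ties[1]
  jt <- jump_test(s, tau_star, alpha = alpha, two_sided = two_sided)
  # interior local minima of the Sn curve other than the global minimum
  sec <- integer(0)
  if (length(sn) >= 3L) {
    interior <- 2:(length(sn) - 1L)
    loc <- interior[sn[interior] <= sn[interior - 1L] & sn[interior] <= sn[interior + 1L]]
    loc <- setdiff(taus[loc], tau_star)
    if (length(loc) > 0 && sn[i_star] > 0) {
      keep <- sn[match(loc, taus)] - sn[i_star] <= prominence * sn[i_star]
      sec <- loc[keep]
    }
  }
  structure(list(
    series = s,
    sn_curve = data.frame(tau = taus, year = s$year[taus], Sn = sn),
    tau_star = tau_star,
    split_year = s$year[tau_star],
    mean_before = mean(s$value[seq_len(tau_star)]),
    mean_after = mean(s$value[(tau_star + 1L):n]),
    v_before = dev["V_before", which(taus == tau_star)],
    v_after = dev["V_after", which(taus == tau_star)],
    t_stat = jt$t_stat,
    critical = jt$critical,
    significant = jt$significant,
    alpha = alpha,
    tied_taus = if (length(ties) > 1L) ties else integer(0),
    no_change_point = no_change,
    secondary_minima = sec
  ), class = "oca")
}

#' @export
print.oca <- function(x, ...) {
  cat("Ordered cluster analysis (change-point scan)\n")
  n <- nrow(x$series)
  cat(sprintf("  series : %d years, %d-%d\n", n, x$series$year[1], x$series$year[n]))
  if (x$no_change_point) {
    cat("  no change point: Sn(tau) is flat across all candidate splits\n")
    return(invisible(x))
  }
  cat(sprintf("  split  : after %d (tau* = %d), Sn(tau*) = %.6g\n",
              x$split_year, x$tau_star, min(x$sn_curve$Sn)))
  cat(sprintf("  means  : %.4f -> %.4f\n", x$mean_before, x$mean_after))
  cat(sprintf("  |T| = %.3f vs %.3f at alpha = %g: %s\n", x$t_stat, x$critical,
              x$alpha, ifelse(x$significant, "significant jump", "not significant")))
  if (length(x$tied_taus) > 0)
    cat("  note   : minimum tied at tau =", paste(x$tied_taus, collapse = ", "),
        "(earliest chosen)\n")
  if (length(x$secondary_minima) > 0)
    cat("  secondary minima at tau =", paste(x$secondary_minima, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.oca <- function(object, ...) {
  print(object)
  cat("\nSn(tau) curve:\n")
  print(object$sn_curve, row.names = FALSE)
  invisible(object)
}

#' @export
plot.oca <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$series$year, x$series$value, type = "b", pch = 16,
       xlab = "year", ylab = "value", main = "annual series", ...)
  if (!x$no_change_point) {
    graphics::abline(v = x$split_year + 0.5, lty = 2, col = "red")
    n <- nrow(x$series)
    graphics::segments(x$series$year[1], x$mean_before, x$split_year, x$mean_before,
                       col = "blue")
    graphics::segments(x$split_year + 1, x$mean_after, x$series$year[n], x$mean_after,
                       col = "blue")
  }
  plot(x$sn_curve$year, x$sn_curve$Sn, type = "b", pch = 1,
       xlab = "split year", ylab = expression(S[n](tau)),
       main = "ordered-cluster objective")
  if (!x$no_change_point)
    graphics::abline(v = x$split_year, lty = 2, col = "red")
  invisible(x)
}

#' Split an annual series at a year
#'
#' The first segment ends at `split_year` inclusive; the second starts the
#' following year. Concatenating the two reproduces the input.
#'
#' @param series An [annual_series()].
#' @param split_year Year strictly inside the span (neither first nor last).
#' @return List of two [annual_series()]: `before`, `after`.
#' @export
segment <- function(series, split_year) {
  s <- as_annual_series(series)
  n <- nrow(s)
  if (split_year <= s$year[1] || split_year >= s$year[n])
    stop("split_year must lie strictly inside ", s$year[1], "..", s$year[n])
  before <- s[s$year <= split_year, ]
  after <- s[s$year > split_year, ]
  list(before = annual_series(before$year, before$value),
       after = annual_series(after$year, after$value))
}
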