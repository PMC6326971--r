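#' Autocorrelogram of a binned activity series
#'
#' Computes the autocorrelation coefficients
#' \deqn{r_k = \frac{\sum_{t=1}^{N-k}(x_t-\bar x)(x_{t+k}-\bar x)}
#'                  {\sum_{t=1}^{N}(x_t-\bar x)^2}}
#' for lags \eqn{k = 0, \dots, K}: the numerator runs over the overlapping
#' part of the series while the denominator is the full sum of squares, so
#' \eqn{r_0 = 1} exactly and \eqn{|r_k| \le 1}. A straight line is also
#' fitted to \eqn{r_k} versus \eqn{k} (lags \eqn{k \ge 1}); a significant
#' slope indicates the linear drift that the rhythmicity index is later
#' adjusted for.
#'
#' @param x An `"activity_series"` or a numeric vector of binned counts.
#' @param max_lag Largest lag in bins; defaults to `floor(N / 2)`, enough to
#'   contain three peaks for periods up to 32 h with two weeks of data.
#'
#' @return An object of class `"correlogram"`: list with `N`, `lags`
#'   (`0:max_lag`), `r`, `trend_intercept`, `trend_slope`, `trend_p`, and
#'   `bin_width_min`.
#' @seealso [rhythmicity_index()]
#' @export
correlogram <- function(x, max_lag = NULL) {
  counts <- if (inherits(x, "activity_series")) x$counts else as.numeric(x)
  bw <- if (inherits(x, "activity_series")) x$bin_width_min else NA_real_
  N <- length(counts)
  if (N < 2L) stop("need at least two bins")
  if (stats::var(counts) == 0) {
    stop("zero-variance series: correlogram undefined")
  }
  if (is.null(max_lag)) max_lag <- N %/% 2L
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= N) stop("'max_lag' must be in [1, N-1]")
  r <- as.numeric(stats::acf(counts, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  r[1L] <- 1                               # exact by definition
  trend <- fit_lag_trend(r[-1L], seq_len(max_lag))
  structure(
    list(N = N, lags = 0:max_lag, r = r,
         trend_intercept = trend$intercept, trend_slope = trend$slope,
         trend_p = trend$p, bin_width_min = bw),
    class = "correlogram")
}

# least-squares line through (k, r_k); p-value of the slope.
# A numerically perfect line has zero residual variance, in which case the
# slope is treated as significant (p = 0) rather than NaN.
fit_lag_trend <- function(r, k) {
  if (length(k) < 3L) {
    return(list(intercept = mean(r), slope = 0, p = 1))
  }
  fit <- stats::lm(r ~ k)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  p <- sm$coefficients["k", "Pr(>|t|)"]
  if (is.nan(p) || is.na(p)) {
    p <- if (abs(cf[["k"]]) > 0 && sum(stats::resid(fit)^2) < 1e-20) 0 else 1
  }
  list(intercept = unname(cf[1L]), slope = unname(cf[2L]), p = p)
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Correlogram: N = %d bins, lags 0..%d\n", x$N, max(x$lags)))
  cat(sprintf("  linear trend: slope %.4g (P = %.3g)\n",
              x$trend_slope, x$trend_p))
  pk <- find_peaks(x$r)
  if (length(pk)) {
    cat("  local maxima at lags:", paste(utils::head(pk, 6L), collapse = ", "),
        if (length(pk) > 6L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$lags, x$r, type = "h", xlab = "lag (bins)",
                 ylab = expression(r[k]), ...)
  graphics::abline(h = c(-2, 2) / sqrt(x$N), lty = 2, col = "grey40")
  graphics::abline(x$trend_intercept, x$trend_slope, col = "red3", lty = 3)
  invisible(x)
}

# Local maxima of r_k at lags k >= 2 (r[0]=1 excludes k=1 by
# construction): s[k] > s[k-1] and s[k] >= s[k+1] (ties toward the smaller
# lag), where s is the correlogram smoothed by a short centered moving
# average (default 5 bins = 2.5 h). The smoothing suppresses one-bin noise
# ripples — which otherwise masquerade as peaks in the flat troughs of
# discrete activity bouts — while leaving genuine peaks (>= 24 bins apart
# for circadian periods) in place. `smooth_window = 1` gives the plain
# unsmoothed rule. `r` is indexed from lag 0; returns lags.
find_peaks <- function(r, smooth_window = 5L) {
  K <- length(r) - 1L
  if (K < 3L) return(integer())
  s <- r
  if (smooth_window > 1L && K > smooth_window) {
    s <- as.numeric(stats::filter(r, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
    s[is.na(s)] <- r[is.na(s)]
  }
  k <- 2:(K - 1L)
  lag_s <- s[k + 1L]                       # smoothed value at lag k
  k[lag_s > s[k] & lag_s >= s[k + 2L]]
}
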