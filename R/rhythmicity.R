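#' Select the third peak of a correlogram
#'
#' The rhythmicity index is the autocorrelation coefficient at the third
#' peak of the correlogram: for a series with period \eqn{\tau} the peaks
#' fall near \eqn{\tau, 2\tau, 3\tau}, so the third local maximum in
#' increasing-lag order tracks the rhythm out to three cycles. A
#' `by_rank` switch instead takes the third-largest local maximum.
#'
#' @param cg A `"correlogram"` object.
#' @param by_rank If `TRUE`, rank peaks by height rather than lag order.
#' @param smooth_window Width (bins) of the moving average used to locate
#'   peaks; the reported coefficient is always the raw `r_k` at the
#'   selected lag. `1` disables smoothing (see Details).
#'
#' @details Peaks are located on a lightly smoothed copy of the correlogram
#'   (5-bin moving average by default) because one-bin noise ripples in the
#'   flat troughs of bout-like activity otherwise register as spurious
#'   local maxima ahead of the true second and third peaks. Smoothing only
#'   affects peak *location*; the RI itself is the unsmoothed coefficient.
#'
#' @return List with `peak_lag` and `ri_raw`, or `NULL` when the correlogram
#'   has fewer than three local maxima (the caller then treats the fly as
#'   arrhythmic and flags it).
#' @export
select_third_peak <- function(cg, by_rank = FALSE, smooth_window = 5L) {
  stopifnot(inherits(cg, "correlogram"))
  peaks <- find_peaks(cg$r, smooth_window = smooth_window)
  if (length(peaks) < 3L) return(NULL)
  heights <- cg$r[peaks + 1L]
  lag <- if (by_rank) peaks[order(-heights)][3L] else peaks[3L]
  list(peak_lag = lag, ri_raw = cg$r[lag + 1L])
}

#' Adjust a rhythmicity index for a linear correlogram trend
#'
#' Correlograms of some flies drift linearly with lag, which inflates or
#' deflates the peak coefficient. When the fitted slope is nominally
#' significant (`trend_p < alpha`), the fitted line's value at the selected
#' peak lag is subtracted from the raw coefficient; otherwise the raw value
#' is returned unchanged.
#'
#' @param cg A `"correlogram"` object.
#' @param peak_lag,ri_raw Selected peak, as from [select_third_peak()].
#' @param alpha Significance level for the trend test (default 0.05).
#'
#' @return List with `ri` and logical `trend_adjusted`.
#' @export
adjust_for_trend <- function(cg, peak_lag, ri_raw, alpha = 0.05) {
  stopifnot(inherits(cg, "correlogram"))
  if (is.finite(cg$trend_p) && cg$trend_p < alpha) {
    line_at_peak <- cg$trend_intercept + cg$trend_slope * peak_lag
    list(ri = ri_raw - line_at_peak, trend_adjusted = TRUE)
  } else {
    list(ri = ri_raw, trend_adjusted = FALSE)
  }
}

#' Classify a rhythmicity index against the 2/sqrt(N) threshold
#'
#' The 95% confidence bound for an autocorrelation coefficient of a white
#' series of length \eqn{N} is \eqn{2/\sqrt N}; an RI at or above the bound
#' is classified rhythmic, strictly below it arrhythmic. With two weeks of
#' 30-min bins (\eqn{N = 672}) the bound is 0.0772.
#'
#' @param ri Rhythmicity index (trend-adjusted).
#' @param N Number of bins entering the correlogram.
#' @return List with `threshold` and logical `is_rhythmic`.
#' @export
classify_rhythmic <- function(ri, N) {
  stopifnot(N > 0)
  threshold <- 2 / sqrt(N)
  list(threshold = threshold, is_rhythmic = is.finite(ri) && ri >= threshold)
}

#' @rdname classify_rhythmic
#' @param line_mean_ri Mean RI of a line-by-sex group, classified by the same
#'   rule (used to call whole line/sex groups arrhythmic).
#' @export
classify_line <- function(line_mean_ri, N) {
  classify_rhythmic(line_mean_ri, N)
}

#' Rhythmicity index of an activity series
#'
#' Runs the full RI procedure on one fly: autocorrelogram, third-peak
#' selection, linear-trend adjustment, and classification against
#' \eqn{2/\sqrt N}. Flies whose correlogram has fewer than three peaks are
#' classified arrhythmic and flagged `"no_third_peak"`.
#'
#' @inheritParams correlogram
#' @param alpha Significance level of the trend adjustment.
#' @param third_by_rank Select the third peak by height rank instead of lag
#'   order (off by default; lag order is the conventional reading).
#' @param smooth_window Moving-average width (bins) for peak location; see
#'   [select_third_peak()].
#'
#' @return An object of class `"rhythmicity"`: list with `ri_raw`, `ri`,
#'   `peak_lag`, `threshold`, `is_rhythmic`, `trend_adjusted`, `N`, `flags`
#'   (character vector) and the underlying `correlogram`.
#' @examples
#' set.seed(1)
#' x <- simulate_fly(period_hours = 24, days = 14, seed = 1)
#' fly <- bin_activity(x$counts)
#' rhythmicity_index(fly)
#' @export
rhythmicity_index <- function(x, max_lag = NULL, alpha = 0.05,
                              third_by_rank = FALSE, smooth_window = 5L) {
  cg <- correlogram(x, max_lag = max_lag)
  flags <- character()
  peak <- select_third_peak(cg, by_rank = third_by_rank,
                            smooth_window = smooth_window)
  if (is.null(peak)) {
    flags <- "no_third_peak"
    res <- list(ri_raw = NA_real_, ri = -Inf, peak_lag = NA_integer_,
                trend_adjusted = FALSE)
  } else {
    adj <- adjust_for_trend(cg, peak$peak_lag, peak$ri_raw, alpha = alpha)
    res <- list(ri_raw = peak$ri_raw, ri = adj$ri, peak_lag = peak$peak_lag,
                trend_adjusted = adj$trend_adjusted)
  }
  cls <- classify_rhythmic(res$ri, cg$N)
  structure(
    c(res, list(threshold = cls$threshold, is_rhythmic = cls$is_rhythmic,
                N = cg$N, flags = flags, correlogram = cg)),
    class = "rhythmicity")
}

#' @export
print.rhythmicity <- function(x, ...) {
  cat("Rhythmicity index\n")
  if (is.na(x$peak_lag)) {
    cat("  no third correlogram peak; classified arrhythmic\n")
  } else {
    cat(sprintf("  RI = %.4f (raw %.4f%s) at peak lag %d\n",
                x$ri, x$ri_raw,
                if (x$trend_adjusted) ", trend-adjusted" else "",
                x$peak_lag))
  }
  cat(sprintf("  threshold 2/sqrt(%d) = %.4f -> %s\n", x$N, x$threshold,
              if (x$is_rhythmic) "rhythmic" else "arrhythmic"))
  invisible(x)
}
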