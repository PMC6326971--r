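#' Fit the full circadian phenotype of one fly
#'
#' The central per-fly estimator: computes the rhythmicity index (with
#' trend adjustment and 2/sqrt(N) classification) and, for rhythmic flies
#' only, the two free-running period estimates — the maximum entropy
#' spectral peak and the chi-square periodogram selection. Arrhythmic flies
#' get no period estimate, matching standard practice.
#'
#' @param x An `"activity_series"` (see [bin_activity()]) or numeric vector
#'   of binned counts.
#' @param ri Named list of arguments passed to [rhythmicity_index()].
#' @param mesa Named list of arguments passed to [estimate_period_mesa()].
#' @param chisq Named list of arguments passed to [estimate_period_chisq()].
#'
#' @return An object of class `"rhythm_fit"`: list with `meta`, `N`,
#'   `rhythmicity` (class `"rhythmicity"`), and — for rhythmic flies —
#'   `mesa` and `chisq` (`"period_estimate"` objects, else `NULL`).
#'   Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' sim <- simulate_fly(period_hours = 25, days = 14, seed = 7)
#' fly <- bin_activity(sim$counts, meta = list(fly_id = "demo"))
#' fit <- fit_rhythm(fly)
#' fit
#' coef(fit)
#' @export
fit_rhythm <- function(x, ri = list(), mesa = list(), chisq = list()) {
  meta <- if (inherits(x, "activity_series")) x$meta else list()
  rhyth <- do.call(rhythmicity_index, c(list(x), ri))
  mesa_est <- chisq_est <- NULL
  if (rhyth$is_rhythmic) {
    mesa_est <- tryCatch(do.call(estimate_period_mesa, c(list(x), mesa)),
                         error = function(e) NULL)
    chisq_est <- tryCatch(do.call(estimate_period_chisq, c(list(x), chisq)),
                          error = function(e) NULL)
  }
  structure(
    list(meta = meta, N = rhyth$N, rhythmicity = rhyth,
         mesa = mesa_est, chisq = chisq_est),
    class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  id <- x$meta$fly_id
  cat("Circadian rhythm fit",
      if (!is.null(id) && !is.na(id)) paste0("(fly ", id, ")"), "\n")
  r <- x$rhythmicity
  cat(sprintf("  RI %.3f vs threshold %.4f -> %s\n",
              if (is.finite(r$ri)) r$ri else NA_real_, r$threshold,
              if (r$is_rhythmic) "rhythmic" else "arrhythmic"))
  if (!is.null(x$mesa)) {
    cat(sprintf("  MESA period  %.2f h%s\n", x$mesa$period_hours,
                if (!x$mesa$interpretable) " (uninterpretable peak)" else ""))
  }
  if (!is.null(x$chisq)) {
    if (x$chisq$significant) {
      cat(sprintf("  chi^2 period %.2f h (Qp %.1f, %d df)\n",
                  x$chisq$period_hours, x$chisq$Qp, x$chisq$dof))
    } else {
      cat("  chi^2 period: no significant candidate\n")
    }
  }
  invisible(x)
}

#' @export
summary.rhythm_fit <- function(object, ...) {
  print(object)
  r <- object$rhythmicity
  if (!is.na(r$peak_lag)) {
    cat(sprintf("  third correlogram peak at lag %d (raw r = %.3f%s)\n",
                r$peak_lag, r$ri_raw,
                if (r$trend_adjusted) ", linear trend removed" else ""))
  }
  if (!is.null(object$mesa)) {
    cat(sprintf("  AR order %d, spectral peak quality %.1fx median\n",
                object$mesa$order, object$mesa$peak_quality))
  }
  invisible(object)
}

#' @export
coef.rhythm_fit <- function(object, ...) {
  r <- object$rhythmicity
  c(ri = if (is.finite(r$ri)) r$ri else NA_real_,
    mesa_period_hours = if (!is.null(object$mesa) &&
                            object$mesa$interpretable)
      object$mesa$period_hours else NA_real_,
    chisq_period_hours = if (!is.null(object$chisq))
      object$chisq$period_hours else NA_real_)
}

#' @export
plot.rhythm_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, if (is.null(x$mesa)) 1 else 3))
  on.exit(graphics::par(old))
  plot(x$rhythmicity$correlogram, main = "correlogram")
  if (!is.null(x$mesa)) plot(x$mesa$spectrum, main = "MESA spectrum")
  if (!is.null(x$chisq)) {
    plot(x$chisq$periodogram, main = "chi-square periodogram")
  }
  invisible(x)
}

#' Phenotype a collection of flies into a per-fly table
#'
#' Applies [fit_rhythm()] to every series and assembles the long phenotype
#' table consumed by the quantitative-genetic analyses. MESA periods
#' flagged uninterpretable and non-significant chi-square scans are
#' reported as `NA`.
#'
#' @param flies List of `"activity_series"` objects (typically the
#'   `retained` element of [qc_filter()]).
#' @inheritParams fit_rhythm
#'
#' @return A data frame with one row per fly: `fly_id`, `line`, `sex`,
#'   `block`, `replicate`, `N`, `ri_raw`, `ri`, `peak_lag`, `threshold`,
#'   `is_rhythmic`, `trend_adjusted`, `mesa_period_hours`, `mesa_quality`,
#'   `chisq_period_hours`, `chisq_Qp`, `flags`.
#' @export
rhythm_phenotypes <- function(flies, ri = list(), mesa = list(),
                              chisq = list()) {
  rows <- lapply(flies, function(fly) {
    fit <- fit_rhythm(fly, ri = ri, mesa = mesa, chisq = chisq)
    r <- fit$rhythmicity
    flags <- r$flags
    if (!is.null(fit$mesa) && !fit$mesa$interpretable) {
      flags <- c(flags, "mesa_uninterpretable")
    }
    data.frame(
      fly_id = fit$meta$fly_id %||% NA_character_,
      line = fit$meta$line %||% NA_character_,
      sex = fit$meta$sex %||% NA_character_,
      block = fit$meta$block %||% NA_integer_,
      replicate = fit$meta$replicate %||% NA_integer_,
      N = fit$N,
      ri_raw = r$ri_raw,
      ri = if (is.finite(r$ri)) r$ri else NA_real_,
      peak_lag = r$peak_lag,
      threshold = r$threshold,
      is_rhythmic = r$is_rhythmic,
      trend_adjusted = r$trend_adjusted,
      mesa_period_hours = if (!is.null(fit$mesa) && fit$mesa$interpretable)
        fit$mesa$period_hours else NA_real_,
      mesa_quality = if (!is.null(fit$mesa)) fit$mesa$peak_quality
        else NA_real_,
      chisq_period_hours = if (!is.null(fit$chisq))
        fit$chisq$period_hours else NA_real_,
      chisq_Qp = if (!is.null(fit$chisq)) fit$chisq$Qp else NA_real_,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
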