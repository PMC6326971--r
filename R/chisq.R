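#' Chi-square periodogram statistic for one candidate period
#'
#' Folds the series at an assumed period of `P` bins and measures how far
#' the per-phase column means depart from the grand mean:
#' \deqn{Q_P = \frac{K N \sum_{h=1}^{P} (M_h - M)^2}
#'                  {\sum_{i=1}^{N} (X_i - M)^2}}
#' where the series is truncated to \eqn{K = \lfloor N/P \rfloor} complete
#' cycles (so \eqn{N = KP} in the formula), \eqn{M_h} is the mean of the
#' \eqn{K} values at phase \eqn{h} and \eqn{M} the grand mean. Under the
#' null of no rhythm at that period, \eqn{Q_P} follows a chi-square
#' distribution with \eqn{P - 1} degrees of freedom.
#'
#' @param x An `"activity_series"` or numeric vector of binned counts.
#' @param period_bins Candidate period in bins (`P >= 2`).
#'
#' @return List with `Qp`, `dof` (`P - 1`), `K` and `N_used` (`K * P`).
#' @export
qp_statistic <- function(x, period_bins) {
  xs <- if (inherits(x, "activity_series")) x$counts else as.numeric(x)
  P <- as.integer(period_bins)
  if (P < 2L) stop("candidate period must be at least 2 bins")
  K <- length(xs) %/% P
  if (K < 1L) stop("candidate period exceeds series length")
  N <- K * P
  xx <- xs[seq_len(N)]
  M <- mean(xx)
  denom <- sum((xx - M)^2)
  if (denom == 0) stop("zero-variance series: Qp undefined")
  Mh <- rowMeans(matrix(xx, nrow = P))
  Qp <- K * N * sum((Mh - M)^2) / denom
  list(Qp = Qp, dof = P - 1L, K = K, N_used = N)
}

#' Chi-square periodogram over a range of candidate periods
#'
#' Scans candidate periods in 1-bin steps across `range_hours` (12-32 h by
#' default), computing [qp_statistic()] and its chi-square critical value at
#' `alpha` for each. A period is selected only if at least one candidate is
#' significant; among significant candidates, the default rule takes the
#' highest raw \eqn{Q_P} (`select = "raw"`). Because the degrees of freedom
#' grow with the candidate period, an alternative rule
#' (`select = "excess"`) maximizes \eqn{Q_P} minus its critical value.
#' No multiplicity correction is applied across candidates.
#'
#' @inheritParams qp_statistic
#' @param bin_width_min Bin width in minutes (taken from an
#'   `"activity_series"` input when available).
#' @param range_hours Candidate period range in hours.
#' @param alpha Per-candidate significance level.
#' @param select Selection rule among significant candidates.
#'
#' @return An object of class `"chisq_periodogram"`: list with
#'   `period_bins`, `period_hours`, `Qp`, `dof`, `critical`, `significant`
#'   (vectors over candidates), and the scalars `selected_period_hours`
#'   (`NA` when no candidate is significant), `selected_Qp`, `selected_dof`,
#'   `any_significant`.
#' @export
chisq_periodogram <- function(x, bin_width_min = NULL,
                              range_hours = c(12, 32), alpha = 0.05,
                              select = c("raw", "excess")) {
  select <- match.arg(select)
  if (is.null(bin_width_min)) {
    bin_width_min <- if (inherits(x, "activity_series")) x$bin_width_min
                     else 30
  }
  bw_h <- bin_width_min / 60
  Ps <- seq.int(ceiling(range_hours[1L] / bw_h),
                floor(range_hours[2L] / bw_h))
  stats_list <- lapply(Ps, function(P) qp_statistic(x, P))
  Qp <- vapply(stats_list, `[[`, numeric(1), "Qp")
  dof <- vapply(stats_list, `[[`, integer(1), "dof")
  crit <- stats::qchisq(1 - alpha, dof)
  sig <- Qp > crit
  if (any(sig)) {
    score <- if (select == "raw") Qp else Qp - crit
    pick <- which(sig)[which.max(score[sig])]
    sel_h <- Ps[pick] * bw_h
    sel_Qp <- Qp[pick]; sel_dof <- dof[pick]
  } else {
    sel_h <- NA_real_; sel_Qp <- NA_real_; sel_dof <- NA_integer_
  }
  structure(
    list(period_bins = Ps, period_hours = Ps * bw_h, Qp = Qp, dof = dof,
         critical = crit, significant = sig, alpha = alpha,
         selected_period_hours = sel_h, selected_Qp = sel_Qp,
         selected_dof = sel_dof, any_significant = any(sig),
         bin_width_min = bin_width_min),
    class = "chisq_periodogram")
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat(sprintf("Chi-square periodogram: %d candidates, %.1f-%.1f h\n",
              length(x$period_bins), min(x$period_hours),
              max(x$period_hours)))
  if (x$any_significant) {
    cat(sprintf("  selected period %.2f h (Qp = %.1f on %d df)\n",
                x$selected_period_hours, x$selected_Qp, x$selected_dof))
  } else {
    cat("  no candidate significant; no period estimated\n")
  }
  invisible(x)
}

#' @export
plot.chisq_periodogram <- function(x, ...) {
  graphics::plot(x$period_hours, x$Qp, type = "l", xlab = "period (h)",
                 ylab = expression(Q[p]), ...)
  graphics::lines(x$period_hours, x$critical, lty = 2, col = "grey40")
  if (x$any_significant) {
    graphics::abline(v = x$selected_period_hours, col = "red3", lty = 3)
  }
  invisible(x)
}

#' Estimate free-running period by the chi-square periodogram
#'
#' Runs [chisq_periodogram()] and wraps the selection as a period estimate.
#' When no candidate reaches significance, `period_hours` is `NA` (no
#' period is estimated for that fly).
#'
#' @inheritParams chisq_periodogram
#' @return An object of class `"period_estimate"` with `method = "chisq"`,
#'   `period_hours` (`NA` when none), `Qp`, `dof`, `significant`, and the
#'   full `"chisq_periodogram"` as `periodogram`.
#' @export
estimate_period_chisq <- function(x, bin_width_min = NULL,
                                  range_hours = c(12, 32), alpha = 0.05,
                                  select = c("raw", "excess")) {
  pg <- chisq_periodogram(x, bin_width_min = bin_width_min,
                          range_hours = range_hours, alpha = alpha,
                          select = select)
  structure(
    list(method = "chisq",
         period_hours = pg$selected_period_hours,
         Qp = pg$selected_Qp, dof = pg$selected_dof,
         significant = pg$any_significant,
         periodogram = pg),
    class = "period_estimate")
}
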