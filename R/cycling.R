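#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution —
#' the mean of the per-sample sorted values, with ties averaged — removing
#' batch effects such as qPCR plate biases. Delegates to
#' `limma::normalizeQuantiles()`.
#'
#' @param x Numeric matrix, one column per sample (e.g. per plate).
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples to quantile-normalize")
  if (nrow(x) == 0L) stop("empty samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Reference-gene normalization
#'
#' Divides each target quantity by the matching reference-gene quantity
#' (e.g. *Actin-5c*) measured in the same sample, yielding dimensionless
#' expression ratios.
#'
#' @param target Numeric vector (or matrix) of target-gene quantities.
#' @param reference Numeric vector of reference-gene quantities, recycled
#'   along `target`; all values must be strictly positive.
#' @return Elementwise ratios `target / reference`.
#' @export
reference_normalize <- function(target, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference quantities must be strictly positive")
  }
  target / reference
}

#' Rank-based cycling test against cosine reference waveforms
#'
#' A Jonckheere-Terpstra-Kendall style test: for every candidate period and
#' phase, the observed quantities are compared with a symmetric cosine
#' sampled at the observation times via Kendall's S statistic, and a
#' one-sided p-value is computed from the tie-corrected normal
#' approximation to the null of no association. The best candidate is
#' reported with its Bonferroni-adjusted p-value (over all period-phase
#' candidates). Being rank-based, the test is invariant to monotone
#' transformations of the quantities.
#'
#' @param quantity Numeric vector of (normalized) expression values.
#' @param time Observation times in hours (replicates share times).
#' @param period_grid Candidate periods in hours (default 24 only, the
#'   natural choice for six 4-h-spaced timepoints over one day).
#' @param phase_grid Candidate peak phases in hours (default 0-22 in 2-h
#'   steps).
#'
#' @return An object of class `"jtk"`: list with `best_period_hours`,
#'   `best_phase_hours`, `p_value` (Bonferroni-adjusted), `p_raw`, `tau`,
#'   `n`, `n_candidates` and `flags` (`"constant"` when all quantities tie,
#'   in which case `p_value = 1`).
#' @examples
#' t <- rep(c(2, 6, 10, 14, 18, 22), each = 3)
#' y <- cos(2 * pi * (t - 10) / 24) + rnorm(length(t), sd = 0.1)
#' jtk_test(y, t)
#' @export
jtk_test <- function(quantity, time, period_grid = 24,
                     phase_grid = seq(0, 22, by = 2)) {
  stopifnot(length(quantity) == length(time))
  n <- length(quantity)
  if (length(unique(time)) < 2L) stop("need at least 2 distinct timepoints")
  if (length(unique(quantity)) == 1L) {
    return(structure(list(best_period_hours = NA_real_,
                          best_phase_hours = NA_real_, p_value = 1,
                          p_raw = 1, tau = NA_real_, n = n,
                          n_candidates = 0L, flags = "constant"),
                     class = "jtk"))
  }
  cand <- expand.grid(period = period_grid, phase = phase_grid)
  best <- list(p = Inf)
  for (i in seq_len(nrow(cand))) {
    ref <- cos(2 * pi * (time - cand$phase[i]) / cand$period[i])
    kt <- kendall_onesided(quantity, ref)
    if (kt$p < best$p) {
      best <- list(p = kt$p, tau = kt$tau,
                   period = cand$period[i], phase = cand$phase[i])
    }
  }
  structure(
    list(best_period_hours = best$period, best_phase_hours = best$phase,
         p_value = min(1, best$p * nrow(cand)), p_raw = best$p,
         tau = best$tau, n = n, n_candidates = nrow(cand),
         flags = character()),
    class = "jtk")
}

# Kendall S between y and reference z, one-sided (concordance) p-value
# from the normal approximation with tie correction and continuity
# correction.
kendall_onesided <- function(y, z) {
  n <- length(y)
  sy <- sign(outer(y, y, "-"))
  sz <- sign(outer(z, z, "-"))
  S <- sum(sy[lower.tri(sy)] * sz[lower.tri(sz)])
  t_y <- table(y); t_z <- table(z)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t_y * (t_y - 1) * (2 * t_y + 5))
  vu <- sum(t_z * (t_z - 1) * (2 * t_z + 5))
  v1 <- sum(t_y * (t_y - 1)) * sum(t_z * (t_z - 1)) / (2 * n * (n - 1))
  v2 <- sum(t_y * (t_y - 1) * (t_y - 2)) * sum(t_z * (t_z - 1) * (t_z - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  d_y <- n * (n - 1) / 2 - sum(t_y * (t_y - 1)) / 2
  d_z <- n * (n - 1) / 2 - sum(t_z * (t_z - 1)) / 2
  tau <- if (d_y > 0 && d_z > 0) S / sqrt(d_y * d_z) else NA_real_
  if (varS <= 0) return(list(p = 1, tau = tau))
  zstat <- (S - sign(S)) / sqrt(varS)   # continuity-corrected
  list(p = stats::pnorm(zstat, lower.tail = FALSE), tau = tau)
}

#' @export
print.jtk <- function(x, ...) {
  if ("constant" %in% x$flags) {
    cat("JTK cycling test: constant course (p = 1)\n")
  } else {
    cat(sprintf(
      "JTK cycling test: best period %g h, phase %g h; adj. p = %.4g (tau %.3f)\n",
      x$best_period_hours, x$best_phase_hours, x$p_value, x$tau))
  }
  invisible(x)
}

#' Cycling scan across an expression table
#'
#' Runs [jtk_test()] for every gene-by-condition group of a long expression
#' table and adjusts across genes within each condition by
#' Benjamini-Hochberg FDR.
#'
#' @param expr Long-format data frame with columns `gene`, `condition`,
#'   `time`, `quantity` (additional columns such as `sex`, `genotype`,
#'   `replicate` are carried as replicates).
#' @inheritParams jtk_test
#' @return Data frame with one row per gene-by-condition:
#'   `gene`, `condition`, `best_period_hours`, `best_phase_hours`,
#'   `p_value`, `adjusted_p`, `tau`, `flags`.
#' @export
cycling_scan <- function(expr, period_grid = 24,
                         phase_grid = seq(0, 22, by = 2)) {
  need <- c("gene", "condition", "time", "quantity")
  missing <- setdiff(need, names(expr))
  if (length(missing)) {
    stop("expression table lacks columns: ", paste(missing, collapse = ", "))
  }
  groups <- unique(expr[c("gene", "condition")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- expr$gene == groups$gene[i] & expr$condition == groups$condition[i]
    res <- jtk_test(expr$quantity[sel], expr$time[sel],
                    period_grid = period_grid, phase_grid = phase_grid)
    data.frame(gene = groups$gene[i], condition = groups$condition[i],
               best_period_hours = res$best_period_hours,
               best_phase_hours = res$best_phase_hours,
               p_value = res$p_value, tau = res$tau,
               flags = paste(res$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  for (cond in unique(out$condition)) {
    sel <- out$condition == cond
    out$adjusted_p[sel] <- bh_fdr(out$p_value[sel])
  }
  out
}
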