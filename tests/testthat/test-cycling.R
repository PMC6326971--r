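test_that("quantile normalization equalizes sample distributions", {
  # identical samples pass through unchanged
  m <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m), m)

  # hand-computed quantile means
  q <- quantile_normalize(cbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(q[, 1], c(2.5, 3.5, 4.5))
  expect_equal(q[, 2], c(2.5, 3.5, 4.5))

  # defining property: identical sorted values in every column; idempotent
  set.seed(14)
  x <- matrix(rlnorm(60), ncol = 4)
  qx <- quantile_normalize(x)
  ref <- sort(qx[, 1])
  for (j in 2:4) expect_equal(sort(qx[, j]), ref)
  expect_equal(quantile_normalize(qx), qx, tolerance = 1e-12)
  # ranks within each sample are preserved
  for (j in 1:4) expect_equal(order(qx[, j]), order(x[, j]))

  expect_error(quantile_normalize(matrix(1, 1, 1)), "at least 2")
  expect_error(quantile_normalize(matrix(numeric(0), 0, 2)), "empty")
})

test_that("reference-gene normalization is an elementwise ratio", {
  expect_equal(reference_normalize(c(2, 4), c(2, 4)), c(1, 1))
  expect_equal(reference_normalize(c(4, 8), c(2, 4)), c(2, 2))
  tgt <- c(3.2, 1.6, 0.8); ref <- c(1.6, 0.4, 0.2)
  expect_equal(reference_normalize(tgt, ref), c(2, 4, 4))
  expect_error(reference_normalize(1:3, c(1, 0, 2)), "positive")
})

test_that("JTK test recovers phase on clean cosines and flags constants", {
  t6 <- rep(c(2, 6, 10, 14, 18, 22), each = 3)

  # constant course: all ties, p = 1
  flat <- jtk_test(rep(2.5, 18), t6)
  expect_equal(flat$p_value, 1)
  expect_true("constant" %in% flat$flags)

  # noiseless cosine peaking at CT10
  y <- 1 + 0.5 * cos(2 * pi * (t6 - 10) / 24)
  res <- jtk_test(y, t6)
  expect_equal(res$best_phase_hours, 10)
  expect_equal(res$best_period_hours, 24)
  expect_lt(res$p_value, 0.05)

  # rank-based: invariant to monotone transformation
  res2 <- jtk_test(exp(3 * y), t6)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res2$best_phase_hours, res$best_phase_hours)
})

test_that("JTK one-sided Kendall p-values agree with cor.test", {
  # without ties in the data, the tie-corrected normal approximation
  # reduces to the standard Kendall normal approximation
  set.seed(22)
  t6 <- rep(c(2, 6, 10, 14, 18, 22), each = 3)
  ref <- cos(2 * pi * (t6 - 10) / 24)
  y <- rnorm(length(t6))
  mine <- circadar:::kendall_onesided(y, ref)
  ct <- suppressWarnings(cor.test(y, ref, method = "kendall",
                                  alternative = "greater"))
  expect_equal(mine$p, unname(ct$p.value), tolerance = 0.02)
})

test_that("detection power rises with amplitude", {
  t6 <- rep(c(2, 6, 10, 14, 18, 22), each = 3)
  power_at <- function(amp, n = 60, seed) {
    set.seed(seed)
    hits <- 0
    for (i in seq_len(n)) {
      y <- 1 + amp * cos(2 * pi * (t6 - 10) / 24) +
        rnorm(length(t6), 0, 0.3)
      if (jtk_test(y, t6)$p_value < 0.05) hits <- hits + 1
    }
    hits / n
  }
  p_small <- power_at(0.1, seed = 1)
  p_mid <- power_at(0.4, seed = 2)
  p_big <- power_at(1.0, seed = 3)
  expect_lte(p_small, p_mid)
  expect_lte(p_mid, p_big)
  expect_gt(p_big, 0.9)
})

test_that("cycling scan runs per gene/condition with BH across genes", {
  genes <- data.frame(gene = c("cyc1", "flat1", "flat2"),
                      amplitude = c(0.8, 0, 0), phase = c(10, 0, 0))
  ex <- simulate_expression(genes, seed = 8)
  expect_equal(sum(ex$gene == "cyc1"), 144L)
  scan <- cycling_scan(ex)
  expect_equal(nrow(scan), 6L)   # 3 genes x 2 conditions
  expect_true(all(scan$adjusted_p >= scan$p_value - 1e-15))
  cyc <- scan[scan$gene == "cyc1", ]
  expect_true(all(cyc$adjusted_p < 0.05))
  expect_true(all(cyc$best_phase_hours %in% c(8, 10, 12)))
})
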