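# Independent oracles used across the suite. Each is a direct, slow
# transcription of the defining formula, kept free of any package internals.

# autocorrelation r_k by explicit double loop
acf_oracle <- function(x, max_lag) {
  N <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  vapply(0:max_lag, function(k) {
    num <- 0
    for (t in seq_len(N - k)) num <- num + (x[t] - xb) * (x[t + k] - xb)
    num / denom
  }, numeric(1))
}

# chi-square periodogram statistic by explicit fold-and-sum
qp_oracle <- function(x, P) {
  K <- length(x) %/% P
  N <- K * P
  x <- x[1:N]
  M <- mean(x)
  Mh <- numeric(P)
  for (h in 1:P) {
    vals <- x[h + P * (0:(K - 1))]
    Mh[h] <- mean(vals)
  }
  K * N * sum((Mh - M)^2) / sum((x - M)^2)
}

# AR spectral density by scalar complex arithmetic, one frequency at a time
ar_density_oracle <- function(a, P, freq) {
  vapply(freq, function(f) {
    s <- 0 + 0i
    for (k in seq_along(a)) s <- s + a[k] * exp(-1i * 2 * pi * f * k)
    P / (Mod(1 - s)^2)
  }, numeric(1))
}

# all local maxima of a correlogram (r indexed from lag 0), brute force
peaks_oracle <- function(r) {
  lags <- integer(0)
  K <- length(r) - 1L
  for (k in 1:(K - 1L)) {
    if (r[k + 1L] > r[k] && r[k + 1L] >= r[k + 2L]) lags <- c(lags, k)
  }
  lags
}

# closed-form EMS solution for the balanced full nested design, written
# directly from the expected-mean-squares table (independent of the
# package's matrix solve). Mean squares are computed from scratch via sums
# of squared group means.
ems_oracle <- function(data, trait = "y") {
  y <- data[[trait]]
  B <- factor(data$block); L <- factor(data$line); R <- factor(data$replicate)
  S <- factor(data$sex)
  N <- length(y)
  gm <- mean(y)
  uss <- function(...) {
    g <- interaction(..., drop = TRUE)
    sum(tapply(y, g, sum)^2 / tapply(y, g, length))
  }
  cf <- sum(y)^2 / N
  n_b <- nlevels(B); n_l <- nlevels(L) / n_b; n_r <- nlevels(R)
  n <- N / (n_b * n_l * 2 * n_r)
  ss <- list(
    B = uss(B) - cf,
    L = uss(B, L) - uss(B),
    R = uss(B, R) - uss(B),
    SL = uss(S, B, L) - uss(B, L) - uss(S, B) + uss(B),
    SR = uss(S, B, R) - uss(B, R) - uss(S, B) + uss(B),
    RL = uss(B, R, L) - uss(B, L) - uss(B, R) + uss(B),
    SRL = uss(S, B, R, L) - uss(S, B, L) - uss(S, B, R) - uss(B, R, L) +
      uss(B, L) + uss(B, R) + uss(S, B) - uss(B),
    E = sum(y^2) - uss(S, B, R, L))
  df <- list(
    B = n_b - 1, L = n_b * (n_l - 1), R = n_b * (n_r - 1),
    SL = n_b * (n_l - 1), SR = n_b * (n_r - 1),
    RL = n_b * (n_l - 1) * (n_r - 1), SRL = n_b * (n_l - 1) * (n_r - 1),
    E = N - 2 * n_b * n_l * n_r)
  ms <- function(k) ss[[k]] / df[[k]]
  s2 <- numeric(0)
  s2["sigma2_error"] <- ms("E")
  s2["sigma2_sexrepline"] <- (ms("SRL") - ms("E")) / n
  s2["sigma2_repline"] <- (ms("RL") - ms("SRL")) / (2 * n)
  s2["sigma2_sexline"] <- (ms("SL") - ms("SRL")) / (n_r * n)
  s2["sigma2_sexrep"] <- (ms("SR") - ms("SRL")) / (n_l * n)
  s2["sigma2_line"] <- (ms("L") - ms("SL") - ms("RL") + ms("SRL")) /
    (2 * n_r * n)
  s2["sigma2_rep"] <- (ms("R") - ms("SR") - ms("RL") + ms("SRL")) /
    (2 * n_l * n)
  s2["sigma2_block"] <- (ms("B") - (s2[["sigma2_error"]] +
    n * s2[["sigma2_sexrepline"]] + 2 * n * s2[["sigma2_repline"]] +
    n_l * n * s2[["sigma2_sexrep"]] + n_r * n * s2[["sigma2_sexline"]] +
    2 * n_l * n * s2[["sigma2_rep"]] + 2 * n_r * n * s2[["sigma2_line"]])) /
    (2 * n_l * n_r * n)
  s2
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# binned series for a simulated fly, shared by many tests
sim_binned <- function(period_hours = 24, amplitude = 1, baseline = 1,
                       days = 13, seed = 1, arrhythmic = FALSE, ...) {
  sim <- simulate_fly(period_hours = period_hours, amplitude = amplitude,
                      baseline = baseline, days = days, seed = seed,
                      arrhythmic = arrhythmic, ...)
  bin_activity(sim$counts)
}
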