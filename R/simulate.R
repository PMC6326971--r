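#' Simulate one fly's activity-monitor record
#'
#' Draws per-minute beam-crossing counts around a non-negative circadian
#' rate function, emulating a two-week constant-darkness recording. Counts
#' are over-dispersed Poisson (negative binomial) by default, since beam
#' crossings come in bursts; an arrhythmic fly has a flat rate, and a death
#' time zeroes all subsequent counts. Generation is seed-deterministic and
#' the truth (period, amplitude, waveform, death time) is returned alongside
#' the counts.
#'
#' @param period_hours Free-running period of the rate function, in hours.
#' @param amplitude Peak rate modulation, counts/min.
#' @param baseline Mean rate level, counts/min.
#' @param waveform `"cosine"` (rectified at zero), `"rectified"`
#'   (half-wave rectified cosine: discrete activity bouts), or `"bimodal"`
#'   (morning and evening peaks, which puts real power at the first
#'   harmonic).
#' @param noise `"nbinom"` (default) or `"poisson"`.
#' @param dispersion Negative-binomial size parameter (smaller = burstier).
#' @param days Recording length in days.
#' @param sampling_interval_min Sampling interval (1 min, as in DAM files).
#' @param arrhythmic If `TRUE`, the rate is flat at `baseline`.
#' @param death_time_hours If non-`NULL`, counts are zero from this time on.
#' @param seed Integer seed; same seed, same series.
#'
#' @return List with `counts` (per-minute), `minutes`, `start_time` and
#'   `truth` (list echoing the generating parameters).
#' @export
simulate_fly <- function(period_hours = 24, amplitude = 1, baseline = 1,
                         waveform = c("cosine", "rectified", "bimodal"),
                         noise = c("nbinom", "poisson"), dispersion = 5,
                         days = 14, sampling_interval_min = 1,
                         arrhythmic = FALSE, death_time_hours = NULL,
                         seed = NULL) {
  waveform <- match.arg(waveform)
  noise <- match.arg(noise)
  if (baseline < 0) stop("baseline must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- round(days * 24 * 60 / sampling_interval_min)
  t_h <- (seq_len(n) - 1L) * sampling_interval_min / 60
  rate <- if (arrhythmic) {
    rep(baseline, n)
  } else {
    phase <- 2 * pi * t_h / period_hours
    switch(waveform,
      cosine = pmax(0, baseline + amplitude * cos(phase)),
      rectified = baseline + amplitude * pmax(0, cos(phase)),
      bimodal = baseline + amplitude * (pmax(0, cos(phase))^2 +
                  0.8 * pmax(0, cos(phase - pi))^2))
  }
  counts <- if (noise == "poisson") {
    stats::rpois(n, rate)
  } else {
    stats::rnbinom(n, mu = rate, size = dispersion)
  }
  if (!is.null(death_time_hours)) {
    counts[t_h >= death_time_hours] <- 0L
  }
  list(counts = as.numeric(counts), minutes = t_h * 60,
       start_time = as.POSIXct("2016-01-01 00:00:00", tz = "UTC"),
       truth = list(period_hours = if (arrhythmic) NA_real_ else period_hours,
                    amplitude = amplitude, baseline = baseline,
                    waveform = waveform, noise = noise,
                    dispersion = dispersion, days = days,
                    arrhythmic = arrhythmic,
                    death_time_hours = death_time_hours, seed = seed))
}

#' Variance-component presets targeting a heritability
#'
#' Builds the component list for [simulate_panel()] from a target
#' broad-sense heritability and cross-sex line-effect correlation, at a
#' fixed total phenotypic variance. The genetic variance
#' `h2 * total` is split between the shared line effect and the
#' sex-by-line effect so that the implied cross-sex correlation
#' \eqn{\sigma^2_L / (\sigma^2_L + \sigma^2_{SL})} equals `r_mf`; the
#' non-genetic remainder is split over block, replicate, replicate-by-line
#' and residual terms in fixed proportions (5/5/10/80%).
#'
#' @param h2 Target broad-sense heritability in `[0, 1)`.
#' @param r_mf Target cross-sex line-effect correlation in `(0, 1]`.
#' @param total Total phenotypic variance (trait units squared).
#' @return Named list of components for [simulate_panel()].
#' @export
panel_components <- function(h2 = 0.43, r_mf = 0.8, total = 0.035) {
  stopifnot(h2 >= 0, h2 < 1, r_mf > 0, r_mf <= 1, total > 0)
  genetic <- h2 * total
  rest <- total - genetic
  list(sigma2_line = genetic * r_mf,
       sigma2_sexline = genetic * (1 - r_mf),
       sigma2_block = rest * 0.05,
       sigma2_rep = rest * 0.05,
       sigma2_repline = rest * 0.10,
       sigma2_error = rest * 0.80)
}

#' Simulate a phenotyped panel of inbred lines
#'
#' Draws a balanced line panel with the standard design shape — lines split
#' into blocks, several replicate measurement rounds per block, a fixed
#' number of flies of each sex per line and replicate — with line, sex-by-
#' line, block, replicate-in-block, replicate-by-line and residual effects
#' drawn from declared variance components. The defaults mirror a
#' 167-line panel in 4 blocks with 3 replicates and 8 flies per sex
#' (48 flies per line) and an RI-like trait with heritability 0.43. A
#' fraction of flies is marked arrhythmic (~12% by default), for use when
#' pairing the panel with activity-level simulation.
#'
#' @param n_lines,blocks,replicates,flies_per_sex Design shape.
#' @param components Named list of true variance components (see
#'   [panel_components()]).
#' @param mu Grand mean of the trait.
#' @param sex_effect Fixed effect added to females (females tend to have
#'   slightly lower RI).
#' @param fraction_arrhythmic Probability a fly is marked arrhythmic.
#' @param trait Name for the trait column.
#' @param seed Integer seed.
#'
#' @return List with `data` (per-fly data frame: `fly_id`, `line`, `sex`,
#'   `block`, `replicate`, trait column, `arrhythmic`, `true_value`) and
#'   `truth` (components, design, realized among-line variances and
#'   realized heritability of the generating draw).
#' @export
simulate_panel <- function(n_lines = 167, blocks = 4, replicates = 3,
                           flies_per_sex = 8,
                           components = panel_components(),
                           mu = 0.3, sex_effect = -0.03,
                           fraction_arrhythmic = 0.12,
                           trait = "y", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- components
  stopifnot(all(unlist(comp) >= 0))
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  line_block <- rep(seq_len(blocks), length.out = n_lines)
  L <- stats::rnorm(n_lines, 0, sqrt(comp$sigma2_line))
  SL <- matrix(stats::rnorm(2 * n_lines, 0, sqrt(comp$sigma2_sexline)),
               nrow = n_lines, dimnames = list(NULL, c("M", "F")))
  B <- stats::rnorm(blocks, 0, sqrt(comp$sigma2_block))
  R <- matrix(stats::rnorm(blocks * replicates, 0, sqrt(comp$sigma2_rep)),
              nrow = blocks)
  RL <- matrix(stats::rnorm(n_lines * replicates, 0,
                            sqrt(comp$sigma2_repline)),
               nrow = n_lines)
  grid <- expand.grid(fly = seq_len(flies_per_sex), sex = c("M", "F"),
                      replicate = seq_len(replicates),
                      line = seq_len(n_lines),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- grid$line
  bi <- line_block[li]
  si <- match(grid$sex, c("M", "F"))
  expected <- mu + ifelse(grid$sex == "F", sex_effect, 0) +
    B[bi] + L[li] + SL[cbind(li, si)] +
    R[cbind(bi, grid$replicate)] + RL[cbind(li, grid$replicate)]
  y <- expected + stats::rnorm(nrow(grid), 0, sqrt(comp$sigma2_error))
  data <- data.frame(
    fly_id = sprintf("%s_%s_r%d_%02d", line_ids[li], grid$sex,
                     grid$replicate, grid$fly),
    line = line_ids[li], sex = grid$sex, block = bi,
    replicate = grid$replicate,
    arrhythmic = stats::runif(nrow(grid)) < fraction_arrhythmic,
    true_value = expected,
    stringsAsFactors = FALSE)
  data[[trait]] <- y
  line_eff <- L + SL                       # per-sex realized line effects
  realized <- list(sigma2_line = stats::var(L),
                   sigma2_sexline = (stats::var(SL[, "M"]) +
                                     stats::var(SL[, "F"])) / 2)
  genetic <- realized$sigma2_line + realized$sigma2_sexline
  realized_h2 <- genetic / (genetic + comp$sigma2_block + comp$sigma2_rep +
                            comp$sigma2_repline + comp$sigma2_error)
  list(data = data,
       truth = list(components = comp,
                    design = c(n_lines = n_lines, blocks = blocks,
                               replicates = replicates,
                               flies_per_sex = flies_per_sex,
                               flies_per_line = 2 * replicates *
                                 flies_per_sex),
                    h2_combined = {
                      g <- comp$sigma2_line + comp$sigma2_sexline
                      g / (g + comp$sigma2_block + comp$sigma2_rep +
                             comp$sigma2_repline + comp$sigma2_error)
                    },
                    realized_h2 = realized_h2,
                    realized_components = realized,
                    line_effects = line_eff,
                    seed = seed))
}

#' Simulate an expression time course
#'
#' Cosine-plus-noise transcript quantities over the full factorial design
#' of a qPCR time-course screen: 2 lighting conditions x 2 sexes x 2
#' genotypes x 3 replicates x 6 timepoints (CT/ZT 2, 6, 10, 14, 18, 22) =
#' 144 samples per gene. Noise is multiplicative lognormal, keeping
#' quantities positive.
#'
#' @param genes Data frame with columns `gene`, `amplitude` (relative, in
#'   `[0, 1)`), `phase` (peak time, hours) and optionally `base` (mean
#'   quantity, default 1).
#' @param conditions,sexes,genotypes,replicates,times Design levels.
#' @param noise_sd Standard deviation of log-quantity noise.
#' @param seed Integer seed.
#'
#' @return Long data frame with columns `gene`, `condition`, `sex`,
#'   `genotype`, `replicate`, `time`, `quantity`; the generating parameters
#'   are attached as attribute `"truth"`.
#' @export
simulate_expression <- function(genes = data.frame(gene = "g1",
                                                   amplitude = 0.5,
                                                   phase = 10),
                                conditions = c("LD", "DD"),
                                sexes = c("M", "F"),
                                genotypes = c("control", "focal"),
                                replicates = 3,
                                times = c(2, 6, 10, 14, 18, 22),
                                noise_sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes$base)) genes$base <- 1
  design <- expand.grid(condition = conditions, sex = sexes,
                        genotype = genotypes,
                        replicate = seq_len(replicates), time = times,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    mu <- g$base * (1 + g$amplitude * cos(2 * pi * (design$time - g$phase) /
                                            24))
    q <- mu * exp(stats::rnorm(nrow(design), 0, noise_sd))
    cbind(data.frame(gene = g$gene, stringsAsFactors = FALSE), design,
          quantity = q)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- genes
  out
}
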