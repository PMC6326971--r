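test_that("one-way variance partition matches the hand EMS solution", {
  d <- data.frame(line = c("A", "A", "B", "B"), y = c(0, 0, 1, 1))
  vc <- variance_components(d, trait = "y", model = "oneway")
  expect_equal(unname(vc$components["sigma2_line"]), 0.5)
  expect_equal(unname(vc$components["sigma2_error"]), 0)

  # all observations identical -> all components zero (up to round-off)
  d2 <- data.frame(line = rep(c("A", "B", "C"), each = 4), y = 2)
  vc2 <- variance_components(d2, trait = "y", model = "oneway")
  expect_lt(max(vc2$components), 1e-12)

  expect_error(variance_components(data.frame(line = "A", y = 1),
                                   trait = "y", model = "oneway"),
               "degenerate")
})

test_that("balanced full-model moments equal the closed-form EMS oracle", {
  for (seed in c(11, 23)) {
    pan <- simulate_panel(n_lines = 8, blocks = 2, replicates = 2,
                          flies_per_sex = 3, seed = seed)
    vc <- variance_components(pan$data, trait = "y", model = "full",
                              method = "moments")
    oracle <- ems_oracle(pan$data)
    oracle[oracle < 0] <- 0
    expect_equal(vc$components[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("moments and REML agree on a balanced design", {
  skip_if_not_installed("lme4")
  pan <- simulate_panel(n_lines = 20, blocks = 2, replicates = 3,
                        flies_per_sex = 4,
                        components = panel_components(h2 = 0.4), seed = 4)
  vm <- variance_components(pan$data, trait = "y", method = "moments")
  vr <- suppressMessages(
    variance_components(pan$data, trait = "y", method = "reml"))
  expect_equal(vm$components, vr$components[names(vm$components)],
               tolerance = 0.02)
  # and REML handles missing values (arrhythmic flies without periods)
  d <- pan$data
  d$y[sample(nrow(d), 40)] <- NA
  vr2 <- suppressMessages(
    variance_components(d, trait = "y", method = "auto"))
  expect_equal(vr2$method, "reml")
  expect_true(all(is.finite(vr2$components)))
})

test_that("components are recovered within 15% on large balanced panels", {
  # the among-line variance of a single draw of 200 line effects differs
  # from its expectation by ~10% (1 sd), so the genetic components are
  # judged against the realized variances in the truth record
  comp <- panel_components(h2 = 0.4, r_mf = 0.8)
  for (s in c(77, 78)) {
    pan <- simulate_panel(n_lines = 200, blocks = 4, replicates = 3,
                          flies_per_sex = 8, components = comp, seed = s)
    vc <- variance_components(pan$data, trait = "y", method = "moments")
    realized <- pan$truth$realized_components
    expect_lt(abs(vc$components[["sigma2_line"]] -
                  realized$sigma2_line) / realized$sigma2_line, 0.15)
    expect_lt(abs(vc$components[["sigma2_sexline"]] -
                  realized$sigma2_sexline) / realized$sigma2_sexline, 0.15)
    expect_lt(abs(vc$components[["sigma2_error"]] -
                  comp$sigma2_error) / comp$sigma2_error, 0.15)
  }
})

test_that("heritability follows the component formulas and stays in [0,1]", {
  expect_equal(heritability(c(sigma2_line = 0, sigma2_sexline = 0,
                              sigma2_error = 1)), 0)
  expect_equal(heritability(c(sigma2_line = 1, sigma2_sexline = 0,
                              sigma2_error = 0)), 1)
  expect_equal(heritability(c(sigma2_line = 0.2, sigma2_sexline = 0.1,
                              sigma2_error = 0.7)), 0.3)
  expect_equal(heritability(c(sigma2_line = 0.2, sigma2_error = 0.6),
                            scope = "sex"), 0.25)
  expect_true(is.na(heritability(c(sigma2_line = 0, sigma2_error = 0))))
  set.seed(5)
  for (i in 1:10) {
    v <- runif(3)
    h <- heritability(c(sigma2_line = v[1], sigma2_sexline = v[2],
                        sigma2_error = v[3]))
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("cross-sex correlation formula, clamping and recovery", {
  expect_equal(as.numeric(cross_sex_correlation(0.5, 0.5, 0.5)), 1)
  expect_equal(as.numeric(cross_sex_correlation(0, 0.3, 0.4)), 0)
  over <- cross_sex_correlation(0.9, 0.5, 0.5)
  expect_equal(as.numeric(over), 1)
  expect_true(attr(over, "clamped"))
  expect_error(cross_sex_correlation(0.5, 0, 0.5), "positive")

  # perfectly shared line effects across sexes -> r_MF near 1
  pan <- simulate_panel(n_lines = 40, blocks = 4, replicates = 3,
                        flies_per_sex = 8,
                        components = panel_components(h2 = 0.4, r_mf = 1),
                        seed = 9)
  pan$data$ri <- pan$data$y
  gs <- genetic_summary(pan$data, traits = "ri", method = "moments")
  expect_gte(gs$traits$r_MF, 0.9)
})

test_that("genetic correlation from line means: limits and null bound", {
  m <- rnorm(20)
  expect_equal(as.numeric(genetic_correlation(m, m)), 1)
  expect_equal(as.numeric(genetic_correlation(m, -m)), -1)
  set.seed(31)
  r <- genetic_correlation(rnorm(100), rnorm(100))
  expect_lt(abs(as.numeric(r)), 0.25)
  expect_error(genetic_correlation(1:2, 2:3), "at least 3")
  expect_error(genetic_correlation(rep(1, 5), rnorm(5)), "zero")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("genetic summary assembles H2, r_MF and a symmetric r_G matrix", {
  set.seed(6)
  pan <- simulate_panel(n_lines = 24, blocks = 4, replicates = 3,
                        flies_per_sex = 4, seed = 6)
  d <- pan$data
  d$ri <- d$y
  d$chisq_period_hours <- 24 + 0.5 * d$y + rnorm(nrow(d), 0, 0.05)
  gs <- genetic_summary(d, traits = c("ri", "chisq_period_hours"),
                        method = "moments")
  expect_equal(dim(gs$r_G), c(2L, 2L))
  expect_equal(gs$r_G, t(gs$r_G))
  expect_equal(diag(gs$r_G), c(ri = 1, chisq_period_hours = 1))
  expect_true(all(gs$traits$H2_combined >= 0 & gs$traits$H2_combined <= 1))
  # strongly shared line effects between the two traits
  expect_gt(gs$r_G["ri", "chisq_period_hours"], 0.5)
})
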