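#' Partition phenotypic variance over line, sex, block and replicate
#'
#' Fits the nested random-effects ANOVA used for panels of inbred lines,
#' `Y = mu + B + S + L(B) + S:L(B) + R(B) + S:R(B) + R:L(B) + S:R:L(B) + e`,
#' with line (`L`), block (`B`) and replicate (`R`) random and sex (`S`)
#' fixed, and returns the variance components. Two estimation paths:
#'
#' * `"moments"` (the primary path, balanced designs): mean squares from
#'   the sequential ANOVA are equated to their expectations and the
#'   triangular expected-mean-squares system is solved exactly. Negative
#'   solutions are truncated to zero and flagged.
#' * `"reml"`: restricted maximum likelihood via \pkg{lme4}, required for
#'   unbalanced data (e.g. period traits, which are missing for arrhythmic
#'   flies). For balanced data with interior solutions the two paths agree.
#'
#' `method = "auto"` (default) uses moments when the design is balanced and
#' REML otherwise.
#'
#' @param data Data frame with columns `line`, `sex`, `block`, `replicate`
#'   and the trait.
#' @param trait Name of the trait column.
#' @param model `"full"` (both sexes, the model above), `"persex"` (one
#'   sex: `Y = mu + B + L(B) + R(B) + R:L(B) + e`), or `"oneway"`
#'   (`Y = mu + L + e`, e.g. for line-mean data).
#' @param sex For `model = "persex"`: which sex to keep (`"M"` or `"F"`).
#' @param method `"auto"`, `"moments"` or `"reml"`.
#'
#' @return An object of class `"varcomp"`: list with `components` (named
#'   numeric; `sigma2_line`, `sigma2_sexline`, `sigma2_block`, `sigma2_rep`,
#'   `sigma2_sexrep`, `sigma2_repline`, `sigma2_sexrepline`, `sigma2_error`
#'   as applicable), `method`, `model`, `truncated` (names of components
#'   truncated at zero), `n_obs` and `design` (cell counts).
#' @seealso [heritability()], [cross_sex_correlation()],
#'   [genetic_summary()]
#' @export
variance_components <- function(data, trait = "y",
                                model = c("full", "persex", "oneway"),
                                sex = NULL,
                                method = c("auto", "moments", "reml")) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (!trait %in% names(data)) stop("no column '", trait, "' in data")
  if (model == "persex") {
    if (is.null(sex)) stop("model = 'persex' needs a 'sex' argument")
    data <- data[data$sex == sex, , drop = FALSE]
  }
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (nrow(data) == 0L) stop("no non-missing observations")
  y <- data[[trait]]

  if (model == "oneway") {
    return(vc_oneway(y, factor(data$line)))
  }

  f <- list(B = factor(data$block), L = factor(data$line),
            R = factor(data$replicate))
  if (model == "full") f$S <- factor(data$sex)
  check_design(f, model)
  bal <- is_balanced(f)
  if (method == "auto") method <- if (bal) "moments" else "reml"
  if (method == "moments" && !bal) {
    stop("moment estimation requires a balanced design; use method = 'reml'")
  }
  vc <- if (method == "moments") vc_moments(y, f, model)
        else vc_reml(y, f, model)
  vc$model <- model
  vc$n_obs <- length(y)
  vc
}

check_design <- function(f, model) {
  if (nlevels(f$B) < 2L) stop("degenerate design: need at least 2 blocks")
  if (nlevels(f$L) < 2L) stop("degenerate design: need at least 2 lines")
  if (nlevels(f$R) < 2L) stop("degenerate design: need at least 2 replicates")
  # lines must be nested in blocks
  lb <- table(f$L, f$B) > 0
  if (any(rowSums(lb) > 1L)) {
    stop("lines must be nested within blocks (each line in one block)")
  }
  invisible(TRUE)
}

is_balanced <- function(f) {
  cells <- do.call(interaction, c(unname(f), drop = FALSE))
  # balance over realized line-in-block structure: equal counts in every
  # line x rep (x sex) cell, equal lines per block, equal reps per block
  lb <- table(f$L, f$B) > 0
  lines_per_block <- colSums(lb)
  counts <- table(droplevels(cells))
  length(unique(lines_per_block)) == 1L && length(unique(counts)) == 1L
}

# --- moments / expected-mean-squares path -------------------------------

# The balanced-data mean squares are obtained from an aov fit on the
# line x sex x replicate cell means (between-cell sums of squares scale by
# the per-cell count n, and the within-cell sum of squares is the
# residual). Fitting on cell means with pre-dropped nested interaction
# factors keeps the model matrix small even for large panels; for balanced
# data the decomposition is exactly the one the full-data nested ANOVA
# gives.
vc_moments <- function(y, f, model) {
  n_b <- nlevels(f$B)
  n_l <- sum(table(f$L, f$B)[, 1L] > 0)        # lines per block
  n_r <- nlevels(f$R)
  cellf <- if (model == "full") list(f$S, f$B, f$L, f$R)
           else list(f$B, f$L, f$R)
  cell <- interaction(cellf, drop = TRUE, lex.order = TRUE)
  n <- length(y) / nlevels(cell)               # flies per cell
  if (n < 2) stop("degenerate design: need at least 2 flies per cell")
  ybar <- tapply(y, cell, mean)
  ss_within <- sum((y - ybar[cell])^2)
  df_within <- length(y) - nlevels(cell)
  idx <- match(levels(cell), cell)             # one row per cell
  cd <- data.frame(ybar = as.numeric(ybar),
                   B = f$B[idx],
                   LB = f$L[idx],
                   RB = droplevels(interaction(f$B[idx], f$R[idx])))
  cd$RLB <- droplevels(interaction(cd$LB, cd$RB))
  if (model == "full") {
    cd$S <- f$S[idx]
    cd$SB <- droplevels(interaction(cd$S, cd$B))
    cd$SLB <- droplevels(interaction(cd$S, cd$LB))
    cd$SRB <- droplevels(interaction(cd$S, cd$RB))
    # SB is included so the sequential SLB and SRB sums of squares are
    # pure sex-by-line and sex-by-replicate interactions; its own mean
    # square is not used (the model has no sex-by-block component).
    fit <- stats::aov(ybar ~ S + B + SB + LB + RB + SLB + SRB + RLB,
                      data = cd)
    terms <- c(B = "B", L = "LB", R = "RB", SL = "SLB", SR = "SRB",
               RL = "RLB", SRL = "Residuals")
    comp_sets <- list(B = "B", L = c("B", "L"), R = c("B", "R"),
                      SL = c("S", "B", "L"), SR = c("S", "B", "R"),
                      RL = c("B", "R", "L"), SRL = c("S", "B", "R", "L"))
    coefs <- c(B = n_l * 2 * n_r * n, L = 2 * n_r * n, R = 2 * n_l * n,
               SL = n_r * n, SR = n_l * n, RL = 2 * n, SRL = n)
    out_names <- c(B = "sigma2_block", L = "sigma2_line", R = "sigma2_rep",
                   SL = "sigma2_sexline", SR = "sigma2_sexrep",
                   RL = "sigma2_repline", SRL = "sigma2_sexrepline")
  } else {
    fit <- stats::aov(ybar ~ B + LB + RB, data = cd)
    terms <- c(B = "B", L = "LB", R = "RB", RL = "Residuals")
    comp_sets <- list(B = "B", L = c("B", "L"), R = c("B", "R"),
                      RL = c("B", "R", "L"))
    coefs <- c(B = n_l * n_r * n, L = n_r * n, R = n_l * n, RL = n)
    out_names <- c(B = "sigma2_block", L = "sigma2_line", R = "sigma2_rep",
                   RL = "sigma2_repline")
  }
  ms_cells <- mean_squares(fit)
  ms_vec <- vapply(terms, function(tt) n * lookup_ms(ms_cells, tt),
                   numeric(1))
  ms_vec <- c(ms_vec, E = ss_within / df_within)
  terms <- c(terms, E = "within")
  k <- length(comp_sets)
  C <- matrix(0, nrow = k + 1L, ncol = k + 1L,
              dimnames = list(names(terms), c(names(comp_sets), "E")))
  for (i in names(comp_sets)) {
    for (j in names(comp_sets)) {
      if (all(comp_sets[[i]] %in% comp_sets[[j]])) C[i, j] <- coefs[[j]]
    }
  }
  C[, "E"] <- 1
  C["E", ] <- c(rep(0, k), 1)
  sol <- solve(C, ms_vec)
  names(sol) <- c(unname(out_names[names(comp_sets)]), "sigma2_error")
  truncated <- names(sol)[sol < 0]
  sol[sol < 0] <- 0
  structure(list(components = sol, method = "moments",
                 truncated = truncated, mean_squares = ms_vec,
                 design = c(blocks = n_b, lines_per_block = n_l,
                            replicates = n_r, per_cell = n)),
            class = "varcomp")
}

mean_squares <- function(fit) {
  tab <- summary(fit)[[1L]]
  stats::setNames(tab[["Mean Sq"]], trimws(rownames(tab)))
}

lookup_ms <- function(ms, term) {
  hit <- match_term(names(ms), term)
  if (is.na(hit)) stop("ANOVA term not found: ", term)
  ms[[hit]]
}

# match "S:B:L" against anova rownames irrespective of factor order
match_term <- function(have, want) {
  want_set <- sort(strsplit(want, ":", fixed = TRUE)[[1L]])
  for (i in seq_along(have)) {
    set <- sort(strsplit(have[i], ":", fixed = TRUE)[[1L]])
    if (identical(set, want_set)) return(i)
  }
  NA_integer_
}

vc_oneway <- function(y, line) {
  a <- nlevels(droplevels(line))
  if (a < 2L) stop("degenerate design: need at least 2 lines")
  fit <- stats::aov(y ~ line)
  ms <- mean_squares(fit)
  n_i <- as.numeric(table(droplevels(line)))
  N <- sum(n_i)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)         # equals n for balanced data
  s2e <- ms[["Residuals"]]
  s2l <- (ms[["line"]] - s2e) / n0
  sol <- c(sigma2_line = s2l, sigma2_error = s2e)
  truncated <- names(sol)[sol < 0]
  sol[sol < 0] <- 0
  structure(list(components = sol, method = "moments", model = "oneway",
                 truncated = truncated, mean_squares = ms,
                 n_obs = N, design = c(lines = a, per_line = n0)),
            class = "varcomp")
}

# --- REML path (lme4) ----------------------------------------------------

vc_reml <- function(y, f, model) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("the REML path needs the 'lme4' package")
  }
  d <- data.frame(y = y, B = f$B, L = f$L,
                  RB = interaction(f$B, f$R, drop = TRUE),
                  RL = interaction(f$L, f$R, drop = TRUE))
  if (model == "full") {
    d$S <- f$S
    d$SL <- interaction(f$S, f$L, drop = TRUE)
    d$SRB <- interaction(f$S, d$RB, drop = TRUE)
    d$SRL <- interaction(f$S, d$RL, drop = TRUE)
    fit <- lme4::lmer(
      y ~ S + (1 | B) + (1 | L) + (1 | SL) + (1 | RB) + (1 | SRB) +
        (1 | RL) + (1 | SRL),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                  check.nobs.vs.nRE = "ignore"))
    map <- c(B = "sigma2_block", L = "sigma2_line", SL = "sigma2_sexline",
             RB = "sigma2_rep", SRB = "sigma2_sexrep",
             RL = "sigma2_repline", SRL = "sigma2_sexrepline")
  } else {
    fit <- lme4::lmer(
      y ~ (1 | B) + (1 | L) + (1 | RB) + (1 | RL),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                  check.nobs.vs.nRE = "ignore"))
    map <- c(B = "sigma2_block", L = "sigma2_line", RB = "sigma2_rep",
             RL = "sigma2_repline")
  }
  vcs <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vcs$vcov, vcs$grp)
  out <- stats::setNames(numeric(length(map) + 1L),
                         c(unname(map), "sigma2_error"))
  for (g in names(map)) out[[map[[g]]]] <- comp[[g]]
  out[["sigma2_error"]] <- comp[["Residual"]]
  structure(list(components = out, method = "reml", truncated = character(),
                 mean_squares = NULL, design = NULL),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("Variance components (%s model, %s)\n", x$model, x$method))
  print(round(x$components, 6))
  if (length(x$truncated)) {
    cat("  truncated at zero:", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' For sexes combined,
#' \eqn{H^2 = (\sigma^2_L + \sigma^2_{SL}) /
#'            (\sigma^2_L + \sigma^2_{SL} + \sigma^2_E)}
#' where \eqn{\sigma^2_E} is the sum of all non-genetic components (block,
#' replicate and interaction terms plus the residual). For a single sex,
#' \eqn{H^2 = \sigma^2_L / (\sigma^2_L + \sigma^2_E)}.
#'
#' @param vc A `"varcomp"` object, or a named numeric vector of components.
#' @param scope `"combined"` (uses line + sex-by-line as the genetic
#'   variance) or `"sex"` (line only, for per-sex or one-way models).
#' @return Heritability in `[0, 1]`, or `NA` if all components are zero.
#' @export
heritability <- function(vc, scope = c("combined", "sex")) {
  scope <- match.arg(scope)
  comp <- if (inherits(vc, "varcomp")) vc$components else vc
  genetic <- comp[["sigma2_line"]] +
    if (scope == "combined" && "sigma2_sexline" %in% names(comp))
      comp[["sigma2_sexline"]] else 0
  total <- sum(comp)
  if (total == 0) return(NA_real_)
  genetic / total
}

#' Cross-sex genetic correlation
#'
#' \eqn{r_{MF} = \sigma^2_L / \sqrt{\sigma^2_{LM} \sigma^2_{LF}}}, where
#' \eqn{\sigma^2_L} is the among-line component with sexes combined and
#' \eqn{\sigma^2_{LM}}, \eqn{\sigma^2_{LF}} are the among-line components
#' from the per-sex reduced models. Estimates outside `[-1, 1]` (possible
#' because the three components are estimated separately) are clamped and
#' flagged via an attribute `clamped`.
#'
#' @param sigma2_L Combined-sex among-line variance component.
#' @param sigma2_LM,sigma2_LF Per-sex among-line variance components
#'   (must be positive).
#' @return `r_MF` in `[-1, 1]`.
#' @export
cross_sex_correlation <- function(sigma2_L, sigma2_LM, sigma2_LF) {
  if (sigma2_LM <= 0 || sigma2_LF <= 0) {
    stop("per-sex line variances must be positive")
  }
  r <- sigma2_L / sqrt(sigma2_LM * sigma2_LF)
  clamped <- r > 1 || r < -1
  r <- min(1, max(-1, r))
  attr(r, "clamped") <- clamped
  r
}

#' Genetic correlation between two traits from line means
#'
#' \eqn{r_G = \mathrm{cov}_{12} / \sqrt{\sigma^2_{L1} \sigma^2_{L2}}}, with
#' the among-line covariance and variances computed from line means (the
#' same quantities a downstream association analysis consumes). Values
#' outside `[-1, 1]` are clamped and flagged.
#'
#' @param means1,means2 Line means of the two traits, aligned by line; pairs
#'   with a missing value are dropped.
#' @return `r_G` in `[-1, 1]` (attribute `clamped`, and `n_lines` used).
#' @export
genetic_correlation <- function(means1, means2) {
  ok <- is.finite(means1) & is.finite(means2)
  m1 <- means1[ok]; m2 <- means2[ok]
  if (length(m1) < 3L) stop("need at least 3 lines with both traits")
  v1 <- stats::var(m1); v2 <- stats::var(m2)
  if (v1 == 0 || v2 == 0) stop("zero among-line variance")
  r <- stats::cov(m1, m2) / sqrt(v1 * v2)
  clamped <- r > 1 || r < -1
  r <- min(1, max(-1, r))
  attr(r, "clamped") <- clamped
  attr(r, "n_lines") <- length(m1)
  r
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR; a thin, range-checked
#' wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Line means of phenotypes
#'
#' Mean trait value per line (and optionally per line-by-sex), computed over
#' flies with a non-missing value — so period means cover rhythmic flies
#' only.
#'
#' @param pheno Per-fly phenotype table (see [rhythm_phenotypes()] or
#'   [simulate_panel()]).
#' @param traits Trait column names.
#' @param by `"line"` or `"line_sex"`.
#' @return Data frame of means, one row per line (or line-by-sex group).
#' @export
line_means <- function(pheno, traits, by = c("line", "line_sex")) {
  by <- match.arg(by)
  keys <- if (by == "line") list(line = pheno$line)
          else list(line = pheno$line, sex = pheno$sex)
  out <- stats::aggregate(pheno[traits], by = keys,
                          FUN = function(v) mean(v, na.rm = TRUE))
  out[order(out$line), , drop = FALSE]
}

#' Heritability and genetic-correlation summary for a panel
#'
#' For each trait: full-model variance components and combined-sex
#' heritability, per-sex components and heritabilities, and the cross-sex
#' correlation; plus the among-line genetic correlation matrix across
#' traits, from line means.
#'
#' @param pheno Per-fly phenotype table with columns `line`, `sex`, `block`,
#'   `replicate` and the traits.
#' @param traits Trait column names (default: RI and both period
#'   estimates when present).
#' @param method Estimation path passed to [variance_components()].
#' @return An object of class `"genetic_summary"`: list with `traits`
#'   (data frame: trait, H2_combined, H2_male, H2_female, r_MF,
#'   sigma2_line, sigma2_sexline), `r_G` (matrix), `varcomp` (per-trait
#'   list of `"varcomp"` objects).
#' @export
genetic_summary <- function(pheno, traits = NULL, method = "auto") {
  if (is.null(traits)) {
    traits <- intersect(c("ri", "mesa_period_hours", "chisq_period_hours"),
                        names(pheno))
  }
  rows <- list(); vcs <- list()
  for (tr in traits) {
    vc <- variance_components(pheno, trait = tr, model = "full",
                              method = method)
    vm <- variance_components(pheno, trait = tr, model = "persex",
                              sex = "M", method = method)
    vf <- variance_components(pheno, trait = tr, model = "persex",
                              sex = "F", method = method)
    s2l <- vc$components[["sigma2_line"]]
    s2lm <- vm$components[["sigma2_line"]]
    s2lf <- vf$components[["sigma2_line"]]
    rmf <- if (s2lm > 0 && s2lf > 0) {
      as.numeric(cross_sex_correlation(s2l, s2lm, s2lf))
    } else NA_real_
    rows[[tr]] <- data.frame(
      trait = tr,
      H2_combined = heritability(vc, "combined"),
      H2_male = heritability(vm, "sex"),
      H2_female = heritability(vf, "sex"),
      r_MF = rmf,
      sigma2_line = s2l,
      sigma2_sexline = vc$components[["sigma2_sexline"]],
      stringsAsFactors = FALSE)
    vcs[[tr]] <- list(combined = vc, male = vm, female = vf)
  }
  lm_tab <- line_means(pheno, traits)
  k <- length(traits)
  rg <- diag(1, k); dimnames(rg) <- list(traits, traits)
  if (k > 1L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      r <- tryCatch(
        as.numeric(genetic_correlation(lm_tab[[traits[i]]],
                                       lm_tab[[traits[j]]])),
        error = function(e) NA_real_)
      rg[i, j] <- rg[j, i] <- r
    }
  }
  structure(list(traits = do.call(rbind, rows), r_G = rg, varcomp = vcs,
                 line_means = lm_tab),
            class = "genetic_summary")
}

#' @export
print.genetic_summary <- function(x, ...) {
  cat("Quantitative-genetic summary\n")
  tab <- x$traits
  tab[-1L] <- lapply(tab[-1L], round, 3)
  print(tab, row.names = FALSE)
  if (nrow(x$r_G) > 1L) {
    cat("\nAmong-line genetic correlations (line means):\n")
    print(round(x$r_G, 3))
  }
  invisible(x)
}
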