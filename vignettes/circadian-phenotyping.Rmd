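---
title: "Circadian phenotyping and quantitative genetics with circadar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian phenotyping and quantitative genetics with circadar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadar)
```

## What this package computes

`circadar` turns raw *Drosophila* activity-monitor recordings —
beam-crossing counts sampled every minute, typically for two weeks in
constant darkness — into the standard circadian phenotypes of behavioral
quantitative genetics, and then partitions the phenotypic variance of a
panel of inbred lines into genetic and environmental components. Three
per-fly statistics are at its core:

* the **rhythmicity index (RI)** — the autocorrelation coefficient at the
  third peak of the fly's activity correlogram, a measure of rhythm
  robustness (not of period);
* the **MESA period** — the dominant peak of the maximum entropy
  (Burg autoregressive) spectral density;
* the **chi-square periodogram period** — the candidate period whose
  folded-cycle column means depart most significantly from the grand mean.

Downstream, nested random-effects ANOVA over line, sex, block and
replicate yields broad-sense heritability \(H^2\), the cross-sex genetic
correlation \(r_{MF}\), and among-line genetic correlations \(r_G\)
between traits. A rank-based cycling test (in the style of JTK_CYCLE)
screens expression time courses for 24-h rhythms.

## The per-fly model and its conventions

Counts are first summed into 30-min bins (`bin_activity()`), which damps
spurious fine-scale structure; a two-week recording gives \(N = 672\)
bins, and after the standard first-day discard (flies recovering from
CO\(_2\) anaesthesia) a 13-day series of 624 bins. Flies whose final run
of zero counts spans at least 24 h are scored dead and excluded
(`qc_filter()`); the 24-h window is configurable since the convention is
lab-specific. All other observations, outliers included, are retained.

### Rhythmicity index

The correlogram uses the full-sum-denominator autocorrelation
\[
r_k = \frac{\sum_{t=1}^{N-k}(x_t-\bar x)(x_{t+k}-\bar x)}
           {\sum_{t=1}^{N}(x_t-\bar x)^2},
\]
so \(r_0 = 1\) exactly and peaks taper by roughly \(1-k/N\) with lag. For
a \(\tau\)-periodic series the peaks fall near \(\tau, 2\tau, 3\tau\);
the RI is \(r_k\) at the **third local maximum in increasing-lag order**,
tracking the rhythm across three full cycles. A `third_by_rank` switch
selects the third-highest peak instead, but lag order is the conventional
reading and the default.

Two numerical points deserve care:

* **Peak location is computed on a 5-bin (2.5-h) moving average of the
  correlogram.** The naive local-maximum rule (\(r_k > r_{k-1}\),
  \(r_k \ge r_{k+1}\), ties to the smaller lag) is exactly recovered with
  `smooth_window = 1`, but on bout-like activity — long inactive phases,
  as in a half-rectified waveform — one-bin noise ripples in the flat
  correlogram troughs register as spurious "peaks" ahead of the true
  second and third crests. In simulation this sent over half of strongly
  rhythmic bout-like flies to meaningless early peaks; with smoothed
  location (the RI itself is always the *raw* \(r_k\) at the selected
  lag) 98–100% of strongly rhythmic flies across waveforms are classified
  correctly while white-noise flies are misclassified at only ~2–6%,
  comfortably inside the nominal 5% of the threshold below.
* If the correlogram has a nominally significant linear trend
  (regression of \(r_k\) on \(k\), \(P < 0.05\)), the fitted line's value
  **at the selected peak's lag** is subtracted from the raw coefficient.
  The alternative reading — recomputing some overall "RI of the line" —
  is less determinate; subtracting the line at the peak lag is the
  interpretation that exactly removes the drift component under the
  additive model, and the output flags when it has been applied.

A fly is rhythmic when its (trend-adjusted) RI reaches \(2/\sqrt N\), the
95% confidence bound for the autocorrelation of a white series
(0.0772 at \(N = 672\)); classification uses the adjusted RI, and the
boundary value counts as rhythmic. Each fly is classified against its own
retained \(N\) (624 after the first-day discard), with the threshold
reported alongside so either convention can be audited. Flies whose
correlogram offers fewer than three peaks are classified arrhythmic and
flagged rather than erroring.

### MESA period

The series is modeled as an autoregressive process
\(X_t = a_1X_{t-1}+\dots+a_pX_{t-p}+Z_t\) fitted by the Burg lattice
recursion (minimizing forward plus backward prediction error; the fit is
always stationary), and the spectral density
\[
S(\omega) = \frac{P}{\bigl|1-\sum_{k=1}^p a_k e^{-i\omega k}\bigr|^2}
\]
is evaluated on 4096 frequencies in \((0, 0.5]\) cycles/bin, with the
argmax refined by local quadratic interpolation. Defaults that matter:

* **AR order**: chosen by AIC over \(p \in \{2,\dots,N/4\}\), the
  standard MESA practice (order strongly affects peak sharpness); an
  explicit `order` overrides. On near-noiseless series the innovation
  variance underflows and AIC decreases without bound, so selection stops
  at the first order whose relative prediction error falls below
  \(10^{-10}\) — a pure cosine is then fitted exactly as AR(2). The floor
  is relative to the series variance, keeping estimates invariant to
  rescaling the counts.
* **Search range**: the global spectral maximum is reported by default.
  Bimodal (morning/evening) activity puts real power at the half-period
  harmonic, and the global-max convention can then return short periods —
  this is a genuine property of the method, and the `bimodal` simulator
  waveform exists precisely to exercise it. An optional
  `range_hours = c(12, 32)` restricts the search to match the chi-square
  convention.
* **Peak quality**: estimates whose peak density is below 10× the median
  density are flagged uninterpretable, standing in for the manual
  inspection of power-spectral plots; flagged flies are excluded from
  line means.

### Chi-square periodogram

For each candidate period \(P\) (bins), the series is truncated to
\(K = \lfloor N/P\rfloor\) complete cycles and
\[
Q_P = \frac{KN\sum_{h=1}^{P}(M_h-M)^2}{\sum_{i=1}^{N}(X_i-M)^2},
\]
with \(M_h\) the phase-column means, \(M\) the grand mean, and \(N = KP\)
the truncated length — the truncation keeps numerator and denominator
self-consistent. \(Q_P\) is referred to \(\chi^2_{P-1}\). Some
periodogram literature scales this statistic differently
(Sokolove–Bushell variants); the form above has null expectation
\(\approx P-1\) and is the form implemented, verbatim. Candidates run
from 12 h to 32 h in 1-bin (30-min) steps; if none is significant at
\(\alpha = 0.05\) no period is reported, otherwise the highest raw
\(Q_P\) among significant candidates wins (an `"excess"` rule maximizing
\(Q_P\) minus its critical value is available because the degrees of
freedom grow with \(P\)). No multiplicity correction is applied across
candidates — deliberately, since the classical procedure applies none;
the practical guard is that periods are only estimated for flies already
classified rhythmic by RI. The family-wise behavior of the uncorrected
scan on pure noise is measured in the test suite and is stable across
seeds.

## Variance partitioning and genetic parameters

The full model is
\(Y = \mu + B + S + L(B) + S{\times}L(B) + R(B) + S{\times}R(B) +
R{\times}L(B) + S{\times}R{\times}L(B) + \varepsilon\), with line, block
and replicate random and sex fixed. The primary estimation path equates
the balanced-design ANOVA mean squares to their expectations and solves
the (triangular) expected-mean-squares system exactly — transparent,
closed-form, and oracle-checkable. The mean squares come from an `aov`
fit on the line×sex×replicate cell means (between-cell sums of squares
scale by the per-cell count; the pooled within-cell sum of squares is the
residual), which is the identical decomposition but keeps the model
matrix small enough for 200-line panels. REML via `lme4` is the second
path, used automatically when the data are unbalanced — notably for
period traits, which are missing for arrhythmic flies; for balanced data
with interior solutions the two paths agree, and the suite checks this.
Negative moment solutions are truncated to zero and flagged.

Heritability and the genetic correlations follow the component formulas
\[
H^2 = \frac{\sigma^2_L+\sigma^2_{SL}}{\sigma^2_L+\sigma^2_{SL}+\sigma^2_E},
\qquad
r_{MF} = \frac{\sigma^2_L}{\sqrt{\sigma^2_{LM}\,\sigma^2_{LF}}},
\qquad
r_G = \frac{\mathrm{cov}_{12}}{\sqrt{\sigma^2_{L1}\,\sigma^2_{L2}}},
\]
with \(\sigma^2_E\) the sum of all non-genetic components, per-sex
heritabilities from the reduced per-sex models, and \(r_G\) computed from
line means — the same quantities a downstream association study consumes.
Because the three components entering \(r_{MF}\) are estimated
separately, the ratio can stray outside \([-1,1]\); such values are
clamped and flagged. Line means of period traits cover rhythmic flies
only.

## Expression cycling

qPCR-style quantities are quantile-normalized across plates (every
sample forced to the mean empirical distribution, ties averaged) and
divided by a reference gene's normalized quantity measured in the same
sample. The cycling test compares observed quantities with symmetric
cosine references sampled at the design timepoints via Kendall's S, with
the tie-corrected, continuity-corrected normal approximation for the
one-sided (concordance) p-value; the best candidate over the period/phase
grid is Bonferroni-adjusted for the grid size, and genes are
BH-FDR-adjusted within condition. Defaults — a single 24-h candidate
period and 2-h phase steps — are the natural resolution for six 4-h
spaced timepoints; both grids are configurable. Being rank-based, the
test is invariant to monotone transformations of the quantities, and a
constant course returns \(p = 1\) with a flag rather than an error.

## What the simulators emulate — and what they do not

`simulate_fly()` draws per-minute counts from a negative binomial around
a non-negative rate function (cosine, half-rectified cosine, or bimodal),
because beam crossings are bursty; dispersion, amplitude, baseline,
death time and arrhythmicity are tunable, and every generator is
seed-deterministic with a machine-readable truth record.
`simulate_panel()` reproduces the design shape of a large inbred-line
study — lines split into 4 blocks, 3 replicate measurement rounds, 8
flies per sex per line and replicate (48 flies/line) — with line,
sex-by-line, block, replicate and replicate-by-line effects drawn from
declared variance components; `panel_components()` converts a target
\(H^2\) and cross-sex correlation into components at a fixed total
variance (defaults give an RI-like trait at \(H^2 = 0.43\), with ~12% of
flies arrhythmic and a small female deficit in RI, matching what is
typical for wild-derived panels). `simulate_expression()` enumerates the
full 2-condition × 2-sex × 2-genotype × 3-replicate × 6-timepoint design
(144 samples per gene) with lognormal noise.

The simulators deliberately omit several features of real recordings:
light-driven activity startle, sleep-bout structure, within-fly
nonstationarity (period drift, senescence), and any genotype–environment
interaction beyond the declared components. Passing calibration tests on
these simulants therefore demonstrates that the estimators are correct
and well-calibrated under the stated statistical model — not that real
recordings satisfy that model.

## Problem sizes and calibration results

The test suite and the acceptance script rerun the calibrations at
moderate scale: 500 white-noise and 200 strongly rhythmic flies for
classification (misclassification must stay within the nominal ~5–7%,
detection at 95%+), 200 flies with true periods uniform on 16–32 h for
period recovery (both estimators achieve median absolute errors well
under 0.5 h; a 31.8-h long-period line is included since slow-running
outlier lines are where period estimators earn their keep), fifteen
40-line panels per heritability regime (\(H^2 \in \{0.17, 0.39, 0.43\}\),
the range spanning period and RI traits in wild-derived fly panels), and
500 null genes for the cycling test's type-I error. These sizes give
stable estimates in seconds; all are parameters, not limits.

## Known limitations

* The moments path requires balance; unbalanced designs silently switch
  to REML (`method = "auto"`), which is the intended behavior but means
  the two paths' small numerical differences can appear between traits of
  the same panel.
* MESA's AR order selection, frequency grid and quality threshold are
  principled defaults, not community standards — published MESA tools do
  not document theirs, so numerical identity with any particular tool is
  not a goal.
* The chi-square periodogram's 30-min candidate step quantizes period
  estimates to 0.5 h; and with the scan capped at 32 h, lines with true
  periods near the cap are estimated at the boundary.
* `run_pipeline()` covers ingest → QC → phenotypes → line means →
  genetic summary; association analyses downstream of line means are out
  of scope by design.
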