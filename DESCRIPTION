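Package: circadar
Title: Circadian Phenotyping and Quantitative Genetics for Fly Activity
    Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying circadian rest/activity rhythms from
    Drosophila activity monitor (Trikinetics DAM) beam-crossing counts and
    for the quantitative-genetic analysis of rhythm phenotypes across panels
    of inbred lines.  Per-fly phenotypes are the autocorrelation-based
    rhythmicity index with linear-trend adjustment and a 2/sqrt(N)
    classification threshold, and two free-running period estimators:
    maximum entropy spectral analysis (Burg autoregressive spectrum) and the
    chi-square periodogram.  Panel-level analyses partition phenotypic
    variance over line, sex, block and replicate by nested ANOVA
    expected-mean-squares (or REML), and compute broad-sense heritability,
    cross-sex genetic correlations and among-line genetic correlations.
    A rank-based (Jonckheere-Terpstra-Kendall style) cycling test with
    quantile and reference-gene normalization supports expression
    time-course screens.  Seed-deterministic simulators for activity
    records, line panels and expression courses allow every stage to be
    exercised and calibrated without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    limma,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
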