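Package: meqtlmr
Title: Methylation QTL Instruments and Two-Sample Mendelian Randomisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase causal-inference workflow linking DNA methylation to
    type 2 diabetes and glycaemic traits. Phase 1 runs covariate-adjusted
    epigenome-wide association studies (EWAS) on methylation M-values with
    genomic-inflation diagnostics, Benjamini-Hochberg FDR and inverse-variance
    fixed-effects meta-analysis across cohorts. Phase 2 builds Mendelian
    randomisation instruments: genotype quality control, cis-meQTL mapping,
    probe-overlap exclusion, greedy LD clumping, cumulative F statistics and a
    confounder screen; causal effects are then estimated per CpG with the Wald
    ratio, fixed- and multiplicative-random-effects inverse-variance weighting,
    MR-Egger, and Cochran/Rucker Q heterogeneity statistics combined in the
    Rucker model-selection framework. Phase 3 triangulates flagged CpGs via
    temporal stability (Bland-Altman), HbA1c-tertile longitudinal analysis with
    Kruskal-Wallis tests, and cis/trans expression-quantitative-trait
    methylation (eQTM) mapping. A two-cohort synthetic generator with recorded
    ground truth (correlated genotypes, meQTL effects, liability-threshold
    disease model, longitudinal methylation and expression) supports
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
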