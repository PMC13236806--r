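---
title: "From methylation discovery to causal inference: the meqtlmr workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From methylation discovery to causal inference: the meqtlmr workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlmr)
```

## The problem and the model

Cross-sectional epigenome-wide association studies (EWAS) find CpG sites whose
methylation tracks type 2 diabetes and glycaemic traits, but association alone
cannot separate cause from consequence: methylation responds to glycaemia,
medication and cellular composition at least as readily as it drives them.
meqtlmr implements a three-phase workflow that moves from discovery to causal
triangulation:

1. **Discovery.** Covariate-adjusted EWAS on methylation M-values for disease
   status and glycaemic traits, with inverse-variance fixed-effects
   meta-analysis across cohorts and Benjamini-Hochberg FDR.
2. **Causal inference.** For each discovered CpG, independent *cis* methylation
   quantitative trait loci (meQTLs) are built into instrumental variables and
   a two-sample Mendelian randomisation (MR) estimate of the CpG's effect on
   disease is computed under the Rucker model-selection framework.
3. **Triangulation.** CpGs flagged causal are probed further: temporal
   stability of their methylation (Bland-Altman), baseline methylation by
   follow-up-HbA1c tertile (Kruskal-Wallis), and cis/trans expression
   quantitative trait methylation (eQTM) mapping.

The MR model treats per-allele SNP effects on methylation, $\gamma_j$ (M-value
units per alternate allele), and on disease, $\Gamma_j$ (log-odds per allele),
as two-sample summary statistics. Each instrument yields a Wald ratio
$\hat\theta_j = \Gamma_j/\gamma_j$; the fixed-effects inverse-variance-weighted
(IVW) estimate combines them with weights $w_j = \gamma_j^2 /
se(\Gamma_j)^2$, which is identical to zero-intercept weighted least squares
of $\Gamma$ on $\gamma$. Cochran's $Q = \sum_j w_j(\hat\theta_j -
\hat\theta)^2$ measures instrument heterogeneity; MR-Egger refits the same
weighted regression with a free intercept, whose deviation from zero measures
directional pleiotropy, leaving the slope as a pleiotropy-robust causal
estimate with residual heterogeneity $Q'$ on $J-2$ degrees of freedom.

### The Rucker decision tree

`rucker_select()` encodes the selection logic:

* one instrument: Wald ratio;
* $Q$ not significant at $\alpha$: report IVW fixed effects;
* $Q$ significant: fit the multiplicative random-effects IVW (same point
  estimate, SE inflated by $\max\{1, \sqrt{Q/(J-1)}\}$); when $J \ge 3$,
  compute the heterogeneity drop $Q - Q'$ and compare with $\chi^2_1$ — a
  significant drop means the Egger intercept absorbs real directional
  pleiotropy, and the Egger slope is reported instead.

All computed statistics are retained in the result regardless of the selected
method; with exactly two heterogeneous instruments the random-effects IVW is
reported and the Q-difference test is marked unavailable. We use $\alpha =
0.05$ for both heterogeneity steps, consistent with the $Q$ p < 0.05 rule the
framework starts from. MR p-values are reported nominally — in this design a
nominal p < 0.05 is read as suggestive evidence — with a BH-FDR column added
for transparency, not for gating.

Several conventions in this tree were genuinely open choices:

* **Wald-ratio SE.** The first-order delta approximation
  $se(\Gamma)/|\gamma|$ is the default (the dominant convention);
  `second_order = TRUE` adds the exposure-uncertainty term
  $\Gamma^2 se(\gamma)^2/\gamma^4$. Because a normal ratio has no finite
  variance, the test suite validates the second-order SE against a robust
  (MAD-based) scale of a million simulated ratios.
* **Random effects.** Multiplicative with an SE floor at the fixed-effects SE;
  an additive random-effects model is unstable for the 2-3 instruments per
  CpG typical here and was rejected.
* **Egger overdispersion.** Egger SEs carry the analogous factor
  $\max\{1, \sqrt{Q'/(J-2)}\}$.
* **Orientation.** `harmonise()` aligns both sides to the alternate allele as
  effect allele (an explicit convention, since summary-statistic orientation
  is otherwise ambiguous), reconciles swapped alleles by sign-flipping, drops
  irreconcilable pairs with a warning, and finally flips pairs so all
  $\gamma_j > 0$ — required by Egger's convention and without effect on
  Wald/IVW.
* **Intervals.** 95% CIs are $\exp(\hat\theta \pm 1.959964\,se)$; no
  small-sample t correction.

## Building instruments

`qc_variants()` applies the standard marker filters: per-marker missingness
> 5%, minor allele frequency < 1%, exact-test Hardy-Weinberg p <= 1e-6
(computed on hard calls after rounding imputed dosages; the exact test rather
than the chi-square for small-count robustness), and imputation INFO < 0.8.

`map_cis_meqtls()` tests every variant within a 2 Mb region centred on each
CpG — interpreted as +/- 1 Mb, consistent with the 1 Mb cis definition used by
the eQTM stage; both stages share one interval utility so the window
arithmetic cannot drift apart. Variants overlapping the CpG dinucleotide
itself (positions `pos` and `pos + 1`) are excluded before testing, since a
polymorphism under the probe corrupts the measurement. Fits are ordinary
least squares of M-value on dosage with the blood covariate set (age, sex,
medication use, cell proportions); the implementation residualises all
methylation and dosage columns on the covariates once
(Frisch-Waugh-Lovell) and recovers per-pair estimates, SEs and p-values that
are exactly those of per-pair `lm()` fits — the test suite asserts equality at
1e-10. A mixed-model fit with a relatedness matrix is out of scope; fixed
covariate adjustment is a documented approximation.

`clump()` is greedy LD clumping: variants are sorted by ascending p (ties
broken by position, then id, so results are deterministic), the best
unassigned variant becomes an index, and every unassigned variant with
$r^2 \ge 0.1$ against it joins that clump. Independence is strict
($r^2 < 0.1$ between indices), and the clumping search radius equals the cis
window since the candidate set is already cis-restricted. `cumulative_f()`
sums the per-instrument marginal $r^2$ (squared partial correlation
$t^2/(t^2 + df)$ of the marginal fit) over the clumped, approximately
independent instruments — a documented approximation to a joint multi-SNP
$R^2$ — and applies $F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$ with the
conventional $F > 10$ admission bar.

`screen_instruments()` regresses each candidate instrument against age, sex,
BMI, waist, hip and smoking and drops instruments with any nominal
association (p < 0.05): a variant tracking a confounder violates the MR
independence assumption. For continuous confounders the p-value is direction-
symmetric; for binary ones we fit logistic confounder-on-dosage. A relaxed
mode screens age and sex only, mirroring a less restrictive complementary
design. Under six independent nominal screens a valid instrument survives
with probability about $0.95^6 \approx 0.74$ — the strict screen trades
instrument count for validity.

## Association engine choices

* **Scales.** Analyses run on M-values, $M = \log_2(\beta/(1-\beta))$; betas
  are clipped to $[10^{-6}, 1-10^{-6}]$ before conversion so fully
  (un)methylated probes stay finite. Stability summaries convert back to
  percent beta, the reporting scale.
* **Binary-outcome EWAS.** The discovery EWAS of disease status fits a linear
  model on the 0/1 label (`gaussian-on-binary`) by default, matching the
  linear-regression convention of array EWAS; maximum-likelihood logistic is
  available. Participants on glucose-lowering medication are excluded before
  fitting — treatment has a strong methylation signature of its own.
* **Cell proportions.** The six leukocyte fractions are compositional (they
  sum to one), so the neutrophil column is dropped from the design to avoid
  rank deficiency.
* **Outcome GWAS.** Default is ML logistic regression of disease on dosage
  with age, sex, leading genetic principal components and BMI; fixed PC
  adjustment stands in for a GRM mixed model. A `gaussian-on-binary` option
  converts the linear coefficient to an approximate log-OR via
  $\beta / (\hat\mu(1-\hat\mu))$ and labels the result approximate. Exposure
  and outcome samples must be disjoint — shared ids are a hard error, because
  sample overlap biases two-sample MR toward the observational estimate.
* **Meta-analysis.** Effect-size (inverse-variance) mode, not z-score mode,
  because downstream MR needs betas and SEs. FDR families are computed per
  trait and per stage (EWAS trait, meQTL, eQTM per tissue), matching the
  per-analysis thresholds of the study design.
* **Complete cases.** Missing values are `NA` in all text formats; every fit
  is complete-case per unit.

## Triangulation choices

Stability works on paired samples on the percent-beta scale, reporting
per-probe means at both time points, their difference, and Bland-Altman
limits of agreement (mean +/- 1.96 SD of per-sample differences).
`tertile_split()` cuts at the empirical 1/3 and 2/3 quantiles with ties
assigned to the lower tertile (deterministic; sizes differ by at most one
without ties). The Kruskal-Wallis test uses mid-ranks with tie correction via
`stats::kruskal.test()`. The tertile analysis includes untreated prevalent
cases by default, with a flag to exclude them. For eQTM cis/trans calls the
gene is anchored at its annotated TSS (strand-aware), and both the FDR < 0.05
tier and a relaxed, explicitly exploratory FDR < 0.2 tier are flagged.

## What the synthetic cohort emulates — and what it does not

The generator encodes the causal structure the analysis assumes:
SNP $\to$ CpG (latent-Gaussian LD blocks thresholded to Hardy-Weinberg
genotype classes, additive $\gamma$ effects), CpG $\to$ liability
$L = \alpha + \sum_j \theta_j M_{ij}$ with an optional direct SNP $\to$
outcome pleiotropy term, and T2D $\sim$ Bernoulli(logistic($L$)) — the
liability-threshold/logistic choice keeps the MR log-OR scale well defined.
$\alpha$ is solved numerically so each cohort hits its target prevalence.
Fasting glucose is affine in liability with standard-logistic noise,
$g = 7 + s(L + \varepsilon)$, so the $\ge 7.0$ mmol/l diagnostic rule
reproduces the Bernoulli label in expectation *exactly*; HbA1c is affine in
glucose; the follow-up HbA1c adds a configurable linear term
(`lambda_follow`) in the centred causal methylation burden — a stand-in, since
no quantitative methylation-to-follow-up model is established. HOMA-S and
HOMA-B use the classic formulas (HOMA-IR $= g \cdot I_{mU}/22.5$, HOMA-S
$= 100/$HOMA-IR, HOMA-B $= 20 I_{mU}/(g-3.5)$), not the Oxford computer
model, which is not available in closed form; glucose draws at or below 3.6
mmol/l are resampled a bounded number of times to keep the HOMA-B denominator
positive.

Defaults mirror the study conditions the workflow targets: a multi-site
discovery cohort of 879 at 4.7% prevalence with methylation at two time
points, a single-site case-enriched meQTL cohort of 606 at 46.2%, a disjoint
outcome-GWAS cohort of 4,120 at 48.7%, cell-proportion means of
(13.7, 21.3, 5.0, 8.3, 8.1, 43.2)% drawn from a Dirichlet with concentration
30, and a desk-scale array of about 2,000 probes over block-correlated
variants rather than 850k. Haplotype-based LD, array batch/plate artefacts,
probe cross-reactivity, cell-type deconvolution error and relatedness are
*not* emulated: passing calibration and recovery tests here demonstrates the
statistical machinery is correct under the assumed causal model, not that the
pipeline is robust to every failure mode of real array data.

## Numerical and reproducibility notes

* All readers/writers round-trip doubles exactly (17 significant digits on
  write, strtod on read); p-values near 1e-300 survive.
* One config seed is deterministically forked per pipeline stage, so
  identical config + seed gives byte-identical outputs and single stages can
  be re-run in isolation; every stage writes a provenance JSON (config hash,
  stage seed, package version).
* Zero-variance units are flagged and skipped rather than raised as errors;
  rank-deficient designs error naming the collinear columns; constant
  covariate columns (e.g. a single recruitment site) are dropped.
* Tie-breaks are deterministic everywhere (clumping order, tertile ties).

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run, by the package's own choice of
simulation size: type-I error on 500 null replicates (exposure n = 600,
outcome n = 4,000, three instruments); IVW coverage and median-OR recovery at
$\theta = \log(0.76)$ on 300 replicates; Rucker branch behaviour on 200
summary-level replicates (J = 10, instrument effects 0.3-1.2 with SEs 0.02,
shared pleiotropy 0.15 in the pleiotropic arm); a null EWAS of 10,000 probes
for the inflation factor; 50 replicates of 500 null meQTL pairs for FDR
control; and a file-based pipeline demonstration at 200 probes with the
default cohort sizes. The coverage check reads on the IVW estimator because
that is the estimator whose nominal behaviour the recovery claim concerns;
the full decision tree occasionally switches to Egger on chance
heterogeneity, and with near-equal instrument strengths the Egger slope is
poorly identified — visible in its wide SEs, and one reason Egger is a
fallback rather than the default.

## Known limitations

* Weak-instrument (NOME) effects: at exposure n = 600 with per-instrument
  $F \approx 60$, IVW coverage runs slightly below nominal (the acceptance
  band 0.93-0.97 reflects this); smaller exposure samples would need the
  second-order Wald SE or stronger instruments.
* The confounder screen is nominal and unadjusted for multiplicity by design;
  it removes ~26% of perfectly valid instruments in exchange for robustness.
* Cumulative F from summed marginal $r^2$ slightly overstates joint
  instrument strength when residual LD remains below the clumping threshold.
* The gaussian-on-binary log-OR conversion is a first-order approximation,
  adequate near 50% case fraction and increasingly rough away from it.
* eQTM and tertile analyses at n = 55-138 are exploratory by construction;
  the relaxed FDR < 0.2 tier exists to surface candidates, not to confirm
  them.
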