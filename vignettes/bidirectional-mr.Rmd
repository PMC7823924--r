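---
title: "Methods: bi-directional two-sample MR of a biomarker and a binary trait"
author: "bidirMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bi-directional two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirMR)
```

# The question and the design

Serum 25-hydroxyvitamin D (25(OH)D) is observationally associated with
depression, but that association is exposed to confounding (lifestyle,
adiposity, time outdoors all move both quantities) and to reverse
causation (depressed people may get less sun and eat differently).
Mendelian randomization (MR) addresses both by using genetic variants as
instruments: alleles are assigned at conception, so variant–outcome
associations are immune to classical confounding and cannot be caused by
the outcome. `bidirMR` implements the full two-sample, bi-directional
battery for this setting:

* **forward**: variants that raise 25(OH)D → does genetically higher
  25(OH)D lower the odds of depression?
* **reverse**: variants that raise depression liability → does genetic
  liability to depression lower 25(OH)D?

In the two-sample design the variant–exposure associations
$(\hat\gamma_j, \sigma_{\gamma j})$ and variant–outcome associations
$(\hat\Gamma_j, \sigma_{\Gamma j})$ come from non-overlapping samples and
are combined at the summary level.

# Estimators

With weights $w_j = \sigma_{\Gamma j}^{-2}$:

* **Wald ratio** (single variant): $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$,
  first-order SE $\sigma_{\Gamma j}/|\hat\gamma_j|$.
* **IVW**: $\hat\beta = \sum w_j \hat\gamma_j \hat\Gamma_j / \sum w_j
  \hat\gamma_j^2$ — identical to the fixed-effect inverse-variance
  meta-analysis of the Wald ratios (this identity is tested numerically on
  random instrument sets). The default *multiplicative random-effects*
  standard error scales the fixed-effect SE by
  $\max(1, \sqrt{Q/(J-1)})$, where $Q$ is the Cochran-type heterogeneity
  statistic; the floor at 1 means heterogeneity can widen but never
  shrink intervals. Fixed vs random is rarely stated in applied reports;
  the never-anti-shrinking default was chosen for that reason.
* **MR-Egger**: weighted least squares of $\hat\Gamma_j$ on
  $\hat\gamma_j$ *with* an intercept, after orienting every pair so
  $\hat\gamma_j \ge 0$. Egger regression is not orientation-invariant, so
  the convention must be declared; the non-negative-exposure-effect
  orientation is the standard one. The intercept estimates average
  directional pleiotropy and its p-value is the pleiotropy test. The
  overdispersion factor is $\max(1, \sqrt{RSS_w/(J-2)})$. With the
  intercept constrained to zero the estimator collapses to IVW exactly, a
  nested-model identity the tests exploit.
* **Weighted median**: order the Wald ratios, form normalized weights
  $p_j \propto \hat\gamma_j^2/\sigma_{\Gamma j}^2$, and interpolate the
  cumulative weight midpoints $S_j = \sum_{i \le j} p_i - p_j/2$ at 0.5.
  Consistent while valid instruments carry more than half the weight.
* **Weighted mode**: weighted normal-kernel density over the ratios with
  bandwidth $h = \varphi \cdot 0.9\min(\mathrm{sd}, \mathrm{mad})
  J^{-1/5}$ ($\varphi = 1$ by default; `mad` uses the 1.4826
  normal-consistency constant), evaluated on a fixed 512-point grid
  spanning the ratios $\pm 3h$; the estimate is the grid argmax.
  The fixed grid makes the argmax bit-reproducible; ties take the first
  (lowest) grid point. Consistent when the largest group of equal-ratio
  instruments is valid.

Median and mode have no convenient closed-form SE; both use a seeded
parametric bootstrap (default 1000 replicates) resampling
$\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{\gamma j}^2)$,
$\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{\Gamma j}^2)$. All p-values
use the normal reference, the usual choice for summary-data MR; this is
declared rather than mixed with t references for determinism across J.

# MR-PRESSO

The global test measures whether the weighted residual sum of squares
around leave-one-out IVW predictions, $RSS = \sum_j w_j (\hat\Gamma_j -
\hat\beta_{(-j)}\hat\gamma_j)^2$, is larger than expected under no
pleiotropy; its null distribution is built by redrawing
$\hat\Gamma_j^* \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma^2_{\Gamma j})$
and $\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma^2_{\gamma j})$ and
recomputing. Residuals are inverse-variance weighted: unweighted
residuals would conflate imprecision with pleiotropy. Per-variant squared
residuals give the outlier test (Bonferroni-adjusted by J, flagged at
0.05); the distortion test compares the percent change of the IVW
estimate after removing the flagged outliers with the changes from
removing random subsets of the same size — the natural reference in a
summary-data setting where individuals cannot be resampled. All
Monte-Carlo p-values use the add-one convention
$(1 + \#\{\cdot\})/(n_{sim}+1)$, so they are valid and never zero.
Defaults: $n_{sim} = 1000$ (p-resolution $10^{-3}$; fewer than 100 is
refused), at least 4 instruments so each leave-one-out IVW keeps 3.

# Harmonization and QC

Variants are matched by identifier only (applied MR uses named lead
variants; no position liftover). Outcome records whose alleles are
swapped relative to the exposure — directly or on the complementary
strand — have their effect sign flipped and allele frequency reflected.
Palindromic variants (A/T, C/G) cannot be aligned by labels; they are
kept only when both allele frequencies fall on the same side of 0.5 and
outside the window $[0.5-w, 0.5+w]$ ($w = 0.08$ by default, a common
conservative choice), in which case the effect alleles are inferred to
coincide; otherwise they are dropped with reason `palindromic`. Every
drop carries a reason and kept + dropped always partitions the input —
both are invariants under test.

QC thresholds (`filterInstruments`) are inclusive — "at least 0.18"
keeps 0.18 — covering minor allele frequency, Hardy–Weinberg p,
imputation INFO and association p. The strong-instrument battery in the
motivating application satisfies MAF ≥ 0.18, HWE p > 0.17 and
INFO ≥ 0.96.

# Reporting scales and power

Causal estimates in the forward direction are log odds ratios per unit
of natural-log exposure; the converting factor $1.5^{\hat\beta}$ re-expresses
them as the odds ratio per 50% higher 25(OH)D. Reverse-direction effects
on the natural-log biomarker are re-expressed as percent change,
$100(e^{\hat\beta}-1)$. Confidence bounds are mapped through the same
monotone transforms (endpoint mapping). Both transforms invert exactly,
which the tests check on value grids.

The binary-outcome power approximation uses
$SE = 1/\sqrt{n\,r^2\,K(1-K)}$ for the log-OR per SD of exposure.
Achieved power uses the exact two-sided normal formula, so power at
$\beta = 0$ equals $\alpha$; the minimal detectable effect uses the
closed form $(z_{1-\alpha/2}+z_{power})\,SE$, which scales exactly as
$1/\sqrt{n}$. The SD of log 25(OH)D is an explicit input
(`sdLogExposure`) because applied reports rarely print it; 0.45 is used
in the worked examples, consistent with a median near 49 nmol/L and an
interquartile range of roughly 34–64.

Fixed-effect inverse-variance meta-analysis pools each method across
outcome cohorts (biobank and consortium); with two cohorts a
random-effects variance estimate would be unstable, so fixed-effect is
the only offered pooling.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is validated.

**Forward.** Genotypes $G_j \sim \text{Binomial}(2, f_j)$, independent
across variants (instruments in applied MR are LD-clumped, so no LD is
modelled). Exposure $X = \sum_j \gamma_j G_j + c_x U + \epsilon$ with a
single standard-normal confounder $U$ — the minimal structure that
creates the confounding MR must defeat — scaled to unit variance with
the instruments explaining `r2Target`. Per-variant effect magnitudes are
drawn uniform then rescaled, since applied sources fix only the total
variance explained. The binary outcome follows
$\text{logit}\,P = \beta_0 + \beta X + \sum_j \alpha_j G_j + c_y U$ with
$\beta_0$ solved numerically for the target case fraction. Defaults: 6
instruments, MAF in [0.18, 0.5], $r^2 = 2.7\%$, prevalence 13%, two
samples of 50,000 — the variance-explained, allele-frequency and
prevalence structure of the motivating data sources at a desk-runnable
sample size.

**Reverse.** Depression liability $L$ is generated like $X$ and
thresholded at its $1-K$ quantile (the standard generative analogue of a
case/control trait); the continuous outcome is
$Y = \beta L + c_y U + \epsilon_y$, also unit variance. Exposure-side
summaries are single-variant *logistic score regressions* (one-step
$U/I$ estimators on the log-OR scale), matching how consortium GWAS
report binary-trait effects; outcome-side summaries are single-variant
linear regressions. Defaults: 44 instruments, MAF in [0.07, 0.5],
liability $r^2 = 0.2\%$, samples of 330,000 and 300,000. The exposure
sample's case fraction defaults to 0.34, not the 13% population
prevalence, because the depression GWAS being emulated is a
case-control meta-analysis (113,154 cases, 218,523 controls) — a
case-enriched sample — and instrument strength depends directly on
$K(1-K)$.

For small per-variant effects the log-OR of a liability effect
$\gamma$ is $\lambda\gamma$ with $\lambda = \phi(t)/(K(1-K))$,
$t = \Phi^{-1}(1-K)$. The IVW estimand per unit log-odds is therefore
$\beta/\lambda$, and `liabilityEffectForPercentChange()` inverts this
chain so a target percent change (e.g. −3.26%) can be injected exactly.

**Pleiotropy regimes** for the direct effects $\alpha_j$: `none` (all
zero), `balanced` (centred to mean zero by construction), `directional`
(non-zero mean, InSIDE holds), `correlated` ($\text{corr}(\alpha,
\gamma) \approx 0.7$ by construction — an InSIDE violation for stressing
the sensitivity battery).

**What the generator does not emulate**: linkage disequilibrium,
imputation artifacts, population stratification, sample overlap,
case-control ascertainment beyond the case-fraction choice, and
selection of instruments by genome-wide significance. The last point
matters for interpretation: spreading 0.2% of liability variance evenly
over 44 variants at these sample sizes yields per-variant F statistics
near 9, so reverse-direction IVW carries a known weak-instrument
attenuation toward the null of roughly $F/(F+1)$; real instrument sets,
being significance-selected, are individually stronger. Passing
recovery tests under these conditions therefore demonstrates correct
implementation under honest weak-instrument noise, not that real-data
estimates are free of weak-instrument bias.

**Observational cohort.** One draw per individual of age group, sex, a
socioeconomic score and a lifestyle score; log-exposure is normal around
$\log 49$ nmol/L with SD 0.45; depression is logistic in log-exposure
and the covariates with the intercept solved for the target prevalence.
The covariate tiers are nested by construction (basic ⊂ socioeconomic ⊂
lifestyle), with one genuinely new adjustment variable per tier — the
real covariate lists are data-specific, and nesting is the property the
tiered analysis needs. The `confounding` knob makes lifestyle raise
25(OH)D while lowering depression risk, reproducing the
crude-to-adjusted attenuation pattern.

# Observational arm choices

* 25(OH)D categories: `<25`, `[25, 50)`, `[50, 75]`, `>75` nmol/L with
  `<25` as reference. The published category labels leave the value 75
  formally unassigned ("≥50 and <75" and ">75"); it is assigned to the
  third category here, and the tie rule is documented at the function.
* `pTrend` is the likelihood-ratio test of the *continuous* log-exposure
  term — applied reports are often ambiguous between this and a
  category-median trend test; the continuous LRT is the declared choice.
* `pCurvature` is the LRT of adding a squared log-exposure term — the
  minimal declared definition of a curvature test.
* Interaction p-values are LRTs of exposure-by-sex and
  exposure-by-age-group product terms.
* Table percentages round half-up to one decimal (matching how published
  cohort tables are formatted); R's default half-even rounding would
  disagree on exact .x5 boundaries.
* Separation or non-convergence in any logistic fit raises an explicit
  error rather than returning unstable estimates.

# Problem sizes used in validation

The test suite validates calibration and recovery at the generator's
default study conditions: 500 null-calibration replicates of the forward
design (type-I error and coverage of IVW), 200 recovery replicates of
the reverse design with a −3.26% injected effect (mean estimate within
3 Monte-Carlo SEs), and 200 + 200 summary-level replicates for the
MR-PRESSO spike and null behaviour at $n_{sim} = 1000$. Summary-level
simulation is used for PRESSO because the test targets the resampling
machinery itself, and for the Egger-intercept recovery check the
exposure effects are taken as known (the NOME condition Egger assumes).
Algebraic identities (IVW = meta-analysis of Wald ratios; Egger nesting
IVW) are checked to $10^{-10}$ on 1000 and 50 random sets respectively.

# Known limitations

* No multivariable MR, SIMEX-corrected Egger, robust/penalized IVW or
  LD-aware (correlated-instrument) IVW.
* No GWAS-VCF input, LD clumping or proxy-variant lookup; inputs are
  pre-clumped summary tables.
* Weak-instrument attenuation is reported honestly rather than
  corrected; no mode of the package applies a bias correction.
* The distortion test's reference distribution conditions on the number
  of flagged outliers; with very small J its resolution is limited.
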