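---
title: "Methods: one-sample MR of vitamin D status and bone outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample MR of vitamin D status and bone outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The problem and the design

Serum 25-hydroxyvitamin D (25OHD) correlates with bone mineral density
(BMD) and bone-turnover markers in cross-sectional data, but such
associations are vulnerable to confounding and reverse causation. The
one-sample Mendelian-randomization (MR) design implemented here uses
vitamin-D-pathway SNPs as instrumental variables: because alleles are
assigned at meiosis, the genetically predicted component of 25OHD is
independent of lifestyle confounders, and a two-stage least squares (2SLS)
regression of an outcome on that component estimates the causal effect —
under the instrumental assumptions (association with the exposure, no
association with confounders, no effect on outcomes except through the
exposure).

`vitdmr` implements the full chain as a pipeline over a postmenopausal
cohort layout: subject exclusion, trimming and transformation, free and
bioavailable 25OHD, SNP quality control and instrument validation, the
observational (OLS) battery, and the causal (2SLS) battery with
diagnostics. Because no individual-level data ship with the package, a
synthetic-cohort generator with *known* causal structure is a first-class
module: every estimator is validated against the truth it generated.

## The synthetic cohort

The generator (`simulate_cohort()`) realizes the minimal structural model
the MR design reasons about. With a latent standard-normal confounder
$U$:

$$\log \text{25OHD} = \mu_x + \textstyle\sum_j \beta_j (g_j - 2p_j) +
  A\cos\!\big(2\pi(m - m_0)/12\big) + aU + e,$$

$$Y_k = \mu_k + \gamma_k(\log \text{25OHD} - \mu_x) + b_k U +
  c^{age}_k(\text{age}-\bar{a}) + c^{bmi}_k(\text{BMI}-\bar{b}) + e_k,$$

where $g_j \in \{0,1,2\}$ are Hardy-Weinberg genotype dosages (counts of
the vitamin-D-*lowering* allele), $\gamma_k$ the causal effect (default
0), and $b_k$ the confounding path. A single shared $U$ is deliberately
the minimal structure that biases OLS while leaving 2SLS consistent — the
property the whole design rests on. $U$ is emitted only in a truth sidecar
that analysis stages never read.

Key default choices, fixed once:

* **Exposure scale.** $\mu_x = \log 18.3$ and residual SD 0.40, giving a
  log-25OHD SD near 0.43 (median 18.3 ng/mL, IQR ≈ 13–24) — the scale of
  a vitamin-D-insufficient postmenopausal cohort.
* **Instrument strength.** Four instruments (lead SNP `rs2282679` in *GC*,
  plus *NADSYN1* `rs12785878`, *CYP2R1* `rs10741657`, *CYP24A1*
  `rs6013897`). Per-allele effects are calibrated so that at n = 1824 the
  lead SNP explains ≈ 1.1% of exposure variance (F ≈ 20) while the other
  three are individually much weaker; the unweighted four-SNP score then
  explains ≈ 0.7% (F ≈ 13) and the externally weighted score ≈ 1.1%.
  The lead-dominated pattern is what makes the unweighted score *weaker*
  than the single SNP (diluting a strong instrument with noisy ones) and
  the weighted score the most efficient — the qualitative ordering such
  studies report. External weights are configuration inputs, as in a real
  analysis where they come from an independent GWAS.
* **Confounding.** $a = 0.15$ and the $b_k$ are set so the *observational*
  adjusted slopes land near 0.047/0.031/0.034 g/cm² per log-unit 25OHD
  for lumbar/femoral-neck/total-hip BMD and −0.103/−0.088/−0.023 for log
  PTH/P1NP/Beta-CTX — i.e. the entire observational signal is
  confounding, matching the null-causal scenario the MR design is meant
  to expose.
* **LD structure.** Three additional SNPs are generated as high-LD
  partners of instruments (target r² 0.95/0.99/0.99) by sampling
  two-locus haplotypes whose frequencies imply the target r²; infeasible
  (MAF, r²) pairs error with the attainable bound. Three further SNPs
  carry small direct effects (−0.017, −0.016, +0.010) so the per-SNP
  association table has realistic near-threshold content.
* **Exclusions.** Two-stage design (disease/medication, then abnormal
  labs among survivors). An exact-count mode reproduces the
  2,013 → −158 → −31 → 1,824 cascade deterministically; a Bernoulli-rate
  mode is available for general use.
* **Covariates.** Age, BMI, height, labs, DBP (log-normal) and albumin
  are drawn independently at the descriptive-table scale of such a
  cohort; their joint correlation structure is not modelled, because no
  stage of the analysis depends on it. Blood-draw month is uniform by
  default; a seasonal cosine (amplitude 0.10, peak in August) makes the
  season adjustment non-trivial.

All randomness flows from one root seed through named substreams
(genotypes, phenotypes, exclusions), so a module can be regenerated
independently and a full cohort is byte-identical under a fixed seed.

What the generator does *not* emulate: genome-wide data, population
structure, genotyping error beyond missingness, assay measurement error,
or non-linear dose–response. Passing tests therefore demonstrate the
estimators' correctness and the design's logic, not robustness to those
real-data complications.

## Preprocessing rules

* **Trimming** is single-pass: values beyond 3.5 sample SDs from the
  sample mean (statistics computed once on the full vector) are set
  missing and subjects are dropped per-analysis, never globally. A
  zero-variance vector keeps everything. Log-scale variables are trimmed
  on the log scale — the transformation is applied first, because the
  trimming rule presumes approximate normality (order of the two steps is
  a convention; it is logged, and at 3.5 SD it moves <1% of points either
  way).
* **Log transformation** covers the skewed panel (25OHD, PTH, Beta-CTX,
  P1NP); originals are kept alongside the `_ln` columns.
* **Descriptives** report mean ± SD or median (Q1, Q3) by a deterministic
  normality rule — |sample skewness| > 1 selects the median branch — with
  quartiles as linearly interpolated order statistics (R type 7). The
  same skewness rule selects ANOVA versus Kruskal-Wallis in the
  quartile-group tests, so the two reporting surfaces never disagree.
* **Season** defaults to the Northern-Hemisphere meteorological mapping
  (Dec–Feb winter, …) and is configurable; season enters models as
  dummies with winter as the reference.
* **Exclusion percentages** are reported at one decimal using two-step
  rounding (to two decimals, then to one, half away from zero), the
  convention of hand-transcribed clinical reports: 158/2013 → 7.85 → 7.9%.

## Free and bioavailable 25OHD

25OHD partitions between the high-affinity carrier DBP, low-affinity
high-capacity albumin, and a free fraction; bioavailable = free +
albumin-bound. Defaults are the standard constants of the free-vitamin-D
literature — $K_{DBP} = 7\times10^8$, $K_{alb} = 6\times10^5$ L/mol, MW
58 000 / 66 430 / 400.6 g/mol — all configurable, since published
analyses vary in the constants they inherit. Two solvers ship:

* **linear** (default): $F = T/(1 + K_{alb}[Alb] + K_{dbp}[DBP])$, valid
  when total 25OHD is far below the DBP binding capacity (in serum the
  molar ratio is ~2%), and the form in common use;
* **exact**: treats DBP binding as saturable and solves the mass balance
  (a quadratic in $F$ with a unique non-negative root).

The two agree to better than the total/capacity ratio in the trace
regime (verified numerically, along with mass-balance closure to 1e-9
relative on random inputs); the exact solver exists for sensitivity
analyses outside that regime. Outputs are free 25OHD in pg/mL and
bioavailable in ng/mL.

## Genetics QC and instrument validation

Dosages are oriented to the vitamin-D-lowering allele throughout;
generator and analysis share this orientation by construction, and the
VCF reader requires the effect allele to be stated per SNP (no strand
inference). QC requires HWE χ² p > 0.05 (plain 1-df test at the sample
allele frequency, no continuity correction — a monomorphic locus is
defined to pass with a warning) *and* genotyping rate strictly above 90%.
LD defaults to the composite (dosage-correlation) r² because genotypes
are unphased; an EM-haplotype estimator is provided as a cross-check, and
the two agree within 0.02 on HWE data. Non-candidate SNPs with r² ≥ 0.8
to an instrument are mapped as proxies (highest r² wins; ties break to
the alphabetically lower candidate) and removed from independent
analysis. The validity screen regresses each potential confounder (age,
BMI, Ca, P, Cr, BUN) and each outcome on each instrument, applies
Benjamini-Hochberg FDR across the whole screen, and passes an instrument
only if nothing survives.

## The causal stage

`tsls()` computes the exposure coefficient twice and cross-asserts the
two routes to 1e-8 (an algebraic identity given shared covariates):

1. **Control function, as specified in the study design**: outcome on the
   first-stage *fitted* exposure, covariates, and the first-stage
   residual.
2. **Matrix 2SLS**: $\hat\beta = (X'P_ZX)^{-1}X'P_Zy$ with homoskedastic
   variance $\hat\sigma^2(X'P_ZX)^{-1}$, $\hat\sigma^2$ from the
   *structural* residuals $y - X\hat\beta$. The reported SE and p come
   from this route; a sandwich variant is deliberately out of scope, as
   the generator is homoskedastic and the era's standard reports were
   model-based.

**Endogeneity testing.** Two statistics are reported. The classical
Hausman contrast $(\hat\beta_{IV}-\hat\beta_{OLS})^2 /
(se_{IV}^2-se_{OLS}^2)$ on $\chi^2_1$ is implemented exactly, including
its degenerate branch (no p when the variance difference is
non-positive). The battery's headline `hausman_p`, however, is the t-test
on the residual term in the control-function regression (1). In that
parameterization the fitted exposure and the residual are orthogonal, so
the residual coefficient estimates the confounded slope carried by the
non-genetic exposure variation with the small SE of an ordinary
regression coefficient. When the instrumented estimate is near zero this
test asks precisely the MR question — is the observational slope real or
confounder-borne? — with far more power than the contrast form, which
inherits the weak-instrument variance of $\hat\beta_{IV}$ and is
frequently degenerate. On null-causal confounded cohorts the residual
test's p-values track the observational p-values, which is the signature
pattern of such studies. Both are returned so users can compare;
FDR is applied within the battery (its own family, alongside the
observational table, the per-SNP table, and the validity screen, each a
family of its own).

**Diagnostics.** The incremental first-stage R² (gain over covariates
alone), the analytic conversion $F = [(n-1-k)/k]\,R^2/(1-R^2)$, and the
regression partial F are all reported. The two F's coincide exactly when
no covariates are present and differ by the covariate-explained share
otherwise; the analytic conversion is the one used in the strength table,
with the relative TSLS/OLS bias approximated by 1/F and F ≤ 10 flagged
weak. The identity `sample_size_inflation()` (n ∝ SE⁻²: a 20% SE drop ↔
a 56% larger sample) quantifies the efficiency argument for weighted
scores.

**Battery layout.** Five outcomes (three BMD sites, log PTH, log P1NP;
Beta-CTX is excluded by default because its observational association is
null, and only verified associations are carried to the causal stage —
configurable) × three models (single lead SNP, unweighted score, weighted
score), with subjects missing any instrument dosage dropped listwise so n
is constant within the battery.

## Numerical and testing choices

* Fits go through `stats::lm`/`lm.fit` (QR); the 2SLS cross-product
  system is solved by Cholesky. Tests verify the matrix route against an
  independently coded closed form to 1e-10 on a fixed 8-row problem.
* BH-FDR wraps `stats::p.adjust(method = "BH")` and is tested against a
  brute-force step-up oracle on 1,000 random vectors.
* Rounding in rendered tables is half-away-from-zero (estimates 3 dp, F
  2 dp, p scientific below 0.001); every rendered number is recoverable
  unrounded from the JSON bundle.
* Simulation-based tests run at the study's own scale (n = 1824; 500
  replicates for the estimator-recovery checks; 1,000 loci for HWE
  uniformity), sizes chosen to keep Monte-Carlo error a small fraction of
  the assertion tolerances.
* Known property: at first-stage F ≈ 20 with mild endogeneity,
  conventional 2SLS confidence intervals cover at slightly *above* the
  nominal 95% — the estimate and its SE are positively correlated under a
  weak instrument, compressing the t-ratio. The coverage check asserts
  the 93–97% band over 500 replicates and sits at the upper edge of it.

## Limitations

Single-ancestry, individual-level, one-sample MR only: no summary-
statistic estimators (MR-Egger, weighted median), no population-
stratification correction, no genotype imputation, and linearity of the
exposure-outcome relation is assumed throughout. The binding-equilibrium
constants are literature defaults, not measured; genotype-specific DBP
affinity is intentionally not modelled. The generator's independence
assumptions (covariates mutually independent, single shared confounder)
mean the pipeline's behaviour under correlated covariate structures or
multiple confounding channels is untested.
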