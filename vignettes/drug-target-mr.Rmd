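---
title: "Drug-target Mendelian randomization with correlated cis instruments"
author: "targetmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with correlated cis instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The scientific problem

When a drug class fails in trials, the failure can sit with the compounds
(inadequate target engagement, off-target action) or with the target itself.
Two evidence streams can separate these explanations. Drug-target Mendelian
randomization (MR) uses genetic variants in or near the gene encoding the
target that associate with the circulating protein's concentration: carriers
experience a lifelong, compound-free perturbation of the target, so the
genetic effect on disease estimates the *on-target* effect of pharmacological
modulation. Compound-stratified meta-analysis of the randomized trials, with
a formal test of between-compound heterogeneity, shows whether the compounds
behave like one another. If the compounds disagree with each other but the
genetically modelled target effect looks beneficial, the failures were
compound-related; if all compounds agree and disagree with the genetics,
something is wrong with the target model.

`targetmr` implements both streams and the comparison between them:

1. **`gwas_io`** — reading, validating, windowing and harmonizing GWAS
   summary statistics;
2. **`instruments`** — MAF and instrument-strength filters, LD estimation
   from a reference dosage panel, greedy clumping;
3. **`mr_core`** — correlated-instrument GLS-IVW estimation, multivariable
   MR, heterogeneity diagnostics, leverage/outlier pruning, canonical
   orientation;
4. **`trial_meta`** — per-compound fixed/random-effects pooling,
   between-compound Cochran Q, meta-regression, funnel coordinates;
5. **`concordance`** — direction-signed `-log10(p)` evidence matrices and
   hierarchical clustering;
6. **`synthetic_data`** — a generator for every input the pipeline consumes,
   so the whole chain is testable without downloads;
7. **`run_pipeline()`** — one-config orchestration with a full run manifest.

## The estimator

Let $b_X$ be the vector of per-variant associations with the exposure
(protein concentration, or a downstream biomarker used as a weighting
trait), $b_Y$ the harmonized associations with the outcome, $s_Y$ their
standard errors, and $\rho$ the signed LD correlation matrix among the
instruments, oriented to the harmonized effect alleles. With

$$\Omega = \mathrm{diag}(s_Y)\,\rho\,\mathrm{diag}(s_Y),$$

the generalized-least-squares inverse-variance-weighted slope and its
standard error are

$$\hat\theta = (b_X^\top \Omega^{-1} b_X)^{-1} b_X^\top \Omega^{-1} b_Y,
\qquad
\mathrm{se}(\hat\theta) = \sqrt{(b_X^\top \Omega^{-1} b_X)^{-1}},$$

the multivariable version replaces $b_X$ by the $m \times k$ matrix of
exposure betas, and the heterogeneity statistic is
$Q = (b_Y - X\hat\theta)^\top \Omega^{-1} (b_Y - X\hat\theta)$ on $m - k$
degrees of freedom. With $\rho = I$ this is the textbook IVW estimator; with
$m = 1$ the Wald ratio. P-values are two-sided normal.

**What $\Omega$ contains — and what it does not.** Only the outcome
standard errors enter the weighting. Exposure betas are treated as fixed.
In the two-sample design this is the standard first-order convention, and
residual weak-instrument error biases the slope toward the null
(conservative) rather than away from it. It has a second consequence worth
knowing: when the outcome GWAS is much larger than the exposure GWAS, the
neglected exposure-noise term inflates the true sampling variance of
$\hat\theta$ by a factor of roughly
$1 + \theta^2 \sigma_X^2 n_Y / (\sigma_Y^2 n_X)$ relative to the reported
$\mathrm{se}^2$, so nominal 95% intervals cover a few points below 95% when
$n_Y \gg n_X$ and $\theta$ is non-trivial. The calibration study
(`analysis/06_calibration.R`, and the acceptance checks) measures exactly
this. The Q-based overdispersion option (`gls_ivw(..., overdispersion =
TRUE)`), which multiplies the SE by $\sqrt{\max(1, Q/(m-k))}$, absorbs such
excess dispersion; it is off by default because the weighting convention
above is the field's reporting standard, and the run manifest records the
flag either way.

## Instrument selection

- **Cis windows.** Instruments come from a narrow window around the
  target-encoding gene (both bounds inclusive, 1-based, build-checked; no
  liftover). `cetp_window()` and `pcsk9_window()` hold the GRCh38 regions
  used for the two worked targets.
- **Harmonization.** Variants are matched on chromosome + position +
  unordered allele pair (rsIDs are carried, never matched on). Swapped
  alleles flip the outcome beta's sign and complement its frequency; strand
  complements are resolved; palindromic variants (A/T, C/G) are kept only
  when both allele frequencies fall outside (0.42, 0.58) and agree on which
  allele is minor, otherwise dropped. A strict drop-all-palindromic mode
  exists. Every decision is logged per variant.
- **Filters.** Minor allele frequency at least 0.01, and per-variant
  instrument strength $F = (b_X/s_X)^2 \ge 15$, the usual guard against
  weak-instrument bias. $F$ here is the single-variant squared Wald ratio.
- **Clumping.** Greedy thinning ranked by the weighting trait's p-value
  (ties broken by position): keep the best-ranked variant, discard anything
  with $r^2$ strictly above 0.40 against any kept variant, repeat.
  Boundary $r^2$ exactly at the threshold is retained. Clumping is re-run
  per outcome on the harmonized intersection, because different outcome
  GWAS cover different variant sets.
- **LD.** Signed Pearson correlations of reference-panel effect-allele
  dosages (columns reflected where the panel's effect allele disagrees with
  the harmonized one). Sample correlation matrices are positive
  semi-definite by construction; externally supplied matrices are repaired
  by flooring eigenvalues at zero (tolerance 1e-8) with a warning recording
  the repair size. Clumping consumes $r^2$; estimation consumes signed $r$.

## Pruning policy

Influence diagnostics run in the whitened design (pre-multiplied by the
symmetric square root of $\Omega^{-1}$, computed by eigen-decomposition so
results are platform-stable): hat values above $3k/m$ flag leverage;
squared standardized residuals with $\chi^2_1$ upper-tail probability below
$0.05/m$ (Bonferroni) flag outliers. The worst offender is removed, the
model refit, and the cycle repeated until nothing is flagged or only
$\max(3, k+1)$ variants remain — the floor is never crossed, and reaching
it warns, since it signals pervasive misfit rather than a few bad variants.
Thresholds are configurable and echoed into the run manifest; removal
one-at-a-time (rather than all flags at once) keeps the floor exact.

## Canonical orientation

Estimates are reported per unit change in the pharmacologically intended
direction: *decreasing* for protein concentration, LDL-C and TG weighting,
*increasing* for HDL-C. `orient_canonical()` records the orientation tag
and negates the estimate and z when flipping; orienting an already-oriented
result with the same specification is the identity.

## Trial meta-analysis

Binary endpoints become log odds ratios from the 2x2 table
($\mathrm{se} = \sqrt{1/a + 1/b + 1/c + 1/d}$, 0.5 added to all cells when
any cell is zero, double-zero trials excluded with a logged reason);
continuous endpoints are between-group differences in percent change from
baseline, pooled on that percent scale, with
$\mathrm{se} = (\mathrm{CI_{hi}} - \mathrm{CI_{lo}})/(2 \times 1.959964)$
when only an interval is reported. Per-compound pooling is inverse-variance
fixed-effect and DerSimonian-Laird random-effects (the moment estimator;
$\tau^2$ floors at zero, where the two models coincide). Between-compound
heterogeneity treats each compound's pooled estimate as one unit in a
Cochran Q on (compounds - 1) degrees of freedom. Meta-regression is
per-trial weighted least squares with a method-of-moments $\tau^2$ on the
regression residuals — note that regressing compound event effects on
compound biomarker effects is itself an instrumental-variable analysis.
Funnel coordinates (effect vs SE with the pooled pseudo-95% cone) support
visual small-study checks; no formal small-study test is fitted.

## Signed log-p evidence and clustering

Evidence cells are $\mathrm{sign}(\hat\theta) \times (-\log_{10} p)$ with
the two-sided normal p floored at a configured truncation point: 1e-16 for
heatmap-style exports, 1e-60 for the clustering matrix (the deeper floor
keeps strongly significant lipid effects distinguishable). A p of 0.05 maps
to 1.3, corresponding to $|z| = 1.96$. Rows (outcomes) missing in any
source are masked and excluded from clustering but retained in the export.
Clustering operates on $\mathrm{sign}(v)\sqrt{|v|}$ by default (configurable
to the raw values), with Euclidean distance and complete linkage — metric
and linkage are genuinely open choices here, so they are configuration,
recorded in the manifest, and no claim is made about reproducing any
specific published leaf order. Dendrograms export as Newick strings.

## The synthetic-data generator

The generator emulates the *statistical structure* the estimators assume,
not any real locus:

- **Genotypes.** Continuous multivariate-normal dosage scores with AR(1)
  LD, $r_{ij} = \rho_{\mathrm{LD}}^{|i-j|}$ (default 0.8 — tight cis-region
  LD). An optional discrete mode thresholds the latent scores into {0,1,2}
  at Hardy-Weinberg genotype frequencies for the drawn allele frequency.
  The reference panel is emitted as dosages in [0, 2]; in continuous mode a
  single affine rescaling is used so the panel's correlations equal the
  genotype scores' correlations exactly.
- **Exposure.** Protein = $G\gamma$ + noise; by default five causal
  variants ($\gamma = 0.15$, every 10th variant), giving single-variant F
  statistics comfortably above 15 at the default exposure GWAS size.
- **Mediators.** Each mediator is $\alpha \times$ protein $+ G\delta$ +
  noise. The direct effects $\delta$ (default 0.15 on a sparse grid offset
  from the protein's causal variants) give mediators distinguishable genetic
  signatures; with $\delta = 0$ all mediator betas are proportional to the
  protein's and joint mediation modelling is unidentifiable. Mediator GWAS
  are drawn in their own independent sample (default 50,000 — biomarker
  GWAS are typically much larger than pQTL GWAS, and multivariable MR needs
  precise mediator betas).
- **Outcome.** Liability = $\theta \times$ protein $+ \sum \beta_j M_j$ +
  noise; analysed as a continuous trait, or thresholded at the configured
  prevalence and analysed per variant by the one-step logistic score
  estimator ($\hat\beta = U/V$, $\mathrm{se} = V^{-1/2}$ with $U$ the score
  and $V$ the null information), the standard fast GWAS approximation on
  the log-odds scale.
- **Samples.** Exposure (default 10,000), outcome (50,000), mediator
  (50,000) and reference (5,000) samples are always drawn independently —
  the two-sample assumption holds by construction. All randomness flows
  from one mandatory seed, and the generating truth is attached to every
  output.
- **Trials.** Per compound, a true percent-change effect per lipid outcome
  and a true log-OR per event outcome; trials draw binomial event counts in
  both arms and normal mean differences with $\mathrm{se} = \mathrm{sd}
  \sqrt{2/n_{\mathrm{arm}}}$. The default compound set mimics four CETP
  inhibitors taken to phase 3 (HDL responses of roughly +130/+132/+52/+29
  percent, LDL responses of -38/-37/-20/-1 percent, study counts 6/4/4/1,
  and event ORs spanning benefit to harm), with 2,500 participants per arm
  and a control event risk of 8%.

What the generator does **not** emulate: realistic cis-region LD (AR(1) is
a caricature), allele-frequency-dependent effect sizes, sample overlap,
population stratification, or assay-specific measurement structure. Passing
the calibration suite therefore demonstrates internal statistical
correctness of the estimators under their stated assumptions, not
robustness to the violations real consortium data can carry.

### Known calibration properties

Measured by `analysis/06_calibration.R` and the acceptance checks, at the
default study conditions (200 replicates for the recovery and null studies,
2,000 for the Q type-I study):

- the end-to-end estimate of $\theta$ is unbiased to within Monte-Carlo
  error, with a genuine but tiny (~1%) attenuation from clump ranking on
  noisy exposure p-values;
- 95% CI coverage sits a few points below nominal for the reason given in
  the estimator section (unpropagated exposure noise with $n_Y \gg n_X$);
  it stays within three binomial standard errors of 0.95;
- the binary-outcome pipeline's z-statistic is near-nominal under the null;
- the between-compound Q test holds its 5% level;
- multivariable MR recovers an active mediator's direct effect and covers
  zero for an inert one at near-nominal rates.

In binary-outcome mode the generating $\theta$ lives on the liability scale
while the pipeline estimates a log-odds slope, so "recover $\theta$"
is only well-posed for continuous outcomes; binary mode is validated by the
scale-free null calibration instead.

## Numerical choices

- $\Omega$ is inverted via Cholesky; failure raises an error advising a
  lower clump threshold rather than silently regularizing.
- The symmetric square root for whitening uses eigen-decomposition with
  eigenvalues floored relative to the largest (1e-12).
- 1.959964 is used for every 95% interval; signed log-p values compute the
  normal tail on the log scale before flooring, so extreme z-statistics do
  not underflow en route to the truncation point.
- Exact ties at the clumping boundary ($r^2 = r^2_{\max}$) are kept;
  p-value ties in ranking break by genomic position, which is what makes
  clumping invariant to input order.
- Collinear multivariable exposures are rejected at condition number 1e8,
  naming the offending exposures; conditional instrument strength is
  reported as per-exposure variance inflation factors in the whitened
  design plus the design's condition number.

## The analysis workflow

The numbered drivers under `analysis/` run the full study on synthetic
data: `01_simulate.R` (inputs), `02_instruments.R` (selection),
`03_mr.R` (univariable + multivariable MR), `04_trial_meta.R`
(compound-stratified pooling, heterogeneity, funnel, meta-regression),
`05_concordance.R` (evidence matrix + clustering), `06_calibration.R`
(simulation calibration). Each writes its tables under `results/` and
prints a short narrative. `run_pipeline()` executes the same chain from a
single YAML config (see `inst/extdata/demo_config.yaml`) with a manifest
capturing the config snapshot, every threshold and default, per-stage
record counts, the seed, and output checksums; re-running a config
reproduces every output bit for bit.

In the demo configuration the mediators are purely protein-mediated
(no direct variant effects), so the univariable biomarker-weighted models
are correctly specified; plant direct effects via the mediation config to
study pruning and Q under deliberate misspecification. Problem sizes in the
tests and drivers (regions of 8-50 variants, GWAS of 3,000-50,000, 200-2,000
replicates) were chosen as the smallest sizes at which the asymptotic
calibration properties are cleanly visible.

## Limitations

- No colocalization, no Egger/median/mode estimators, no Steiger filtering,
  no liftover, no literature retrieval: deliberately out of scope.
- The percent-change-from-baseline scale is pooled as reported; no attempt
  is made to re-derive subject-level variability.
- Cross-target magnitude comparisons (e.g. a protein measured in ug/ml vs
  one in log ng/ml) are left to the user: estimates carry unit labels and
  per-unit scales are never silently rescaled.
- MVMR in a single cis region is weakly identified whenever mediator
  genetic signatures are nearly proportional; the reported VIFs and
  condition number make this visible, and estimates with large VIFs should
  be read as such.
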