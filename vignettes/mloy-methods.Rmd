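---
title: "Detecting mosaic loss of chromosome Y and testing its causal role"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic loss of chromosome Y and testing its causal role}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mloyr)
```

Mosaic loss of chromosome Y (mLOY) is the most common somatic chromosomal
alteration in ageing men: a clonal subpopulation of cells — typically
leucocytes — loses its Y chromosome entirely. mloyr implements the three
measurement and inference layers needed to study mLOY in a disease cohort:
a bulk whole-genome-sequencing proxy for the per-subject mosaic fraction, a
single-cell read-ratio call with covariate association models, and a
bidirectional two-sample Mendelian-randomisation (MR) suite for causal
questions. Every input the pipeline consumes can be generated synthetically
with known ground truth, so each layer is testable end to end without any
external data.

## The bulk copy-number statistic

For a male sample, the copy number on chromosome Y is defined as

$$\mathrm{CN}_Y = \frac{\bar d_{\mathrm{MSY}}}{\bar d_{\mathrm{denom}}},$$

the mean per-base read depth over the male-specific region of chromosome Y
(MSY — chrY minus both pseudoautosomal regions, whose sequence is shared
with chrX) divided by the mean depth over a diploid denominator. Two
denominator dialects are supported: the 22 autosomes (`autosomes22`, the
primary definition) and chromosome 20 alone (`chr20`, for cohorts where
only per-chromosome summary depths are released). Zero-coverage bases count
in the denominator of each mean, so the statistic is a region-normalised
rate comparable across samples; it is invariant to global depth rescaling.

A no-loss male has one Y per diploid genome, so CN$_Y \approx 0.5 m$ where
$m \in (0,1]$ is an effective MSY mappability/calling factor; a mosaic
fraction $f$ of Y-less cells scales this to $0.5\,m\,(1-f)$.
`estimate_mosaic_fraction()` inverts that relation against a no-loss
reference, clamped to $[0,1]$.

Cohort grouping uses the mean-minus-SD rule: the threshold is the cohort
mean minus one sample standard deviation (n−1 denominator) of CN$_Y$, and a
sample is called mLOY when its value is **strictly below** the threshold —
a value exactly at the boundary is non-mLOY. Read filtering defaults to
MAPQ ≥ 10 with duplicates and secondary/supplementary alignments excluded,
since unique MSY mapping is the premise of the statistic; all three
settings are configurable. Depth can come from an indexed BAM (via a
CIGAR-aware pileup) or from a precomputed `sample_id, region_set,
mean_depth` table, which keeps cohort-level analysis independent of
alignment files.

Open choices made here: MSY coordinates are not universal, so the default
is GRCh38 chrY minus PAR1/PAR2 with a BED override; heterochromatic Yq12 is
not excluded (it contributes length but little unique mapping, which the
$m$ factor absorbs); and the sample SD uses the conventional n−1
denominator.

## Single-cell mLOY calling and association

Per cell, the analogous statistic is the ratio of reads (or UMIs) on
chromosome-Y features to reads on autosomal features. A cell is called
mLOY exactly when that ratio is zero — no chrY reads at all. Cells with
zero autosomal reads carry no information and are dropped with a log.
Because chrY expression is sparse, a retained-Y cell with mean chrY count
$\lambda_y$ still yields a technical zero with probability
$e^{-\lambda_y}$, so at true loss fraction $f$ the observed zero-ratio
proportion converges to

$$f + (1 - f)\,e^{-\lambda_y}.$$

This zero-inflation law is asserted by the tests and bounds what a zero
can mean: per-cell calls are only trustworthy where $\lambda_y$ is large,
while cohort-level contrasts remain valid at any $\lambda_y$ because the
technical-zero rate is shared across groups.

Association uses one logistic regression of the binary per-cell call per
covariate (disease type, lineage, or cell identity) against a reference
level (control), with Wald 95% intervals, Benjamini–Hochberg FDR across
the levels of that covariate, and significance at FDR < 0.05. Cells are
pooled across subjects without random effects, matching the per-figure
reporting convention of comparable analyses; an optional within-subject
design is available for the paired fibrotic-region question, where the
model adds subject indicators and contrasts more- versus less-fibrotic
samples of the same subject. Levels with no mLOY-positive or no
mLOY-negative cells are completely separated and are reported as
unestimable rather than silently dropped. Multiple samples from one
subject are collapsed by pooling cells, which preserves read totals and
makes the pooled mLOY proportion the cell-count-weighted mean of the
per-sample proportions.

For downstream differential expression, comparison groups are the mLOY
cells versus the "high-Y" comparator: non-mLOY disease cells whose ratio
is at or above the 75th percentile of non-mLOY ratios. The percentile uses
the interpolated sample quantile whose worked boundary (ratios 0.01–0.04
give cutoff 0.0375) fixes the convention (R type 6), with ties included by
≥. Fitting the expression models themselves is out of scope; the package
emits the group assignment.

## The Mendelian-randomisation suite

Instruments are selected at genome-wide significance (p < 5×10⁻⁸, strict)
with per-SNP strength F = (β/se)² > 10, then LD-clumped greedily by
ascending p within a 10,000 kb window at r² < 0.001; without an LD matrix
the clump falls back to distance-only pruning with a warning.
Harmonisation aligns outcome effects to the exposure's effect allele,
flipping swapped or strand-complemented alleles and dropping palindromic
variants whose effect-allele frequency falls in [0.42, 0.58] on either
side (outside the band they are aligned by frequency); irreconcilable
allele pairs are dropped with a reason.

Per SNP, the Wald ratio is $\hat\theta_j = \beta_{Yj}/\beta_{Xj}$ with
first-order standard error $se_{Yj}/|\beta_{Xj}|$. The five estimators:

* **IVW** — inverse-variance-weighted mean of Wald ratios. The
  multiplicative random-effects flavour (the main estimate) inflates the
  fixed-effect SE by $\max(1, \sqrt{Q/\mathrm{df}})$, so heterogeneity
  beyond chance widens the interval but never narrows it. Cochran's
  $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on J−1 df and
  $I^2 = \max(0, (Q-\mathrm{df})/Q)$ summarise heterogeneity.
* **MR-Egger** — weighted regression of outcome on exposure betas with an
  intercept, after orienting exposure effects non-negative; the intercept
  estimates average directional pleiotropy and its t-test (J−2 df) is the
  pleiotropy test; SEs carry the same $\max(1,\cdot)$ residual-scale
  floor. Its slope is unbiased under InSIDE even when IVW is not — but
  only the spread of instrument strengths identifies the intercept, so
  power collapses when all instruments have similar β_X.
* **Weighted median** — the standardised-cumulative-weight interpolation
  estimator, consistent while ≥ 50% of weight is valid; its SE comes from
  a seeded parametric bootstrap (default 1000 draws of
  $\theta_j^* \sim N(\hat\theta_j, se_j^2)$).
* **MR-Lasso** — per-SNP L1-penalised intercepts
  $\min_{\theta,\alpha}\sum_j w_j(\beta_{Yj}-\alpha_j-\theta\beta_{Xj})^2
  + \lambda\|\alpha\|_1$, solved by coordinate descent (exact
  soft-threshold updates). λ follows the heterogeneity stopping rule:
  scanning a geometric λ path downward, the first (largest) λ whose
  zero-intercept set has Q at or below its 95% χ² quantile is kept;
  variants with non-zero intercepts are removed and the post-selection
  estimate is IVW on the remainder. Note the rule accepts the valid set
  at the 95th percentile of Q, so when pleiotropic effects blend into
  sampling noise the retained set can legitimately keep residual
  heterogeneity — the heterogeneity collapse it is known for is a
  property of the outlier regime, where invalid effects are many SEs
  from zero.
* **MR-PRESSO** — leave-one-out IVW residual sums of squares compared
  with a seeded parametric null (default 1000 replicates; raising this is
  necessary for Bonferroni-resolved outlier tests when J is large, since
  the empirical p floor is 1/(reps+1)); flagged outliers are removed and
  the corrected estimate is IVW on the rest.

Leave-one-out analysis re-estimates with each SNP omitted and flags
omissions that change the significance conclusion. A suite outcome is
labelled robust only when all five point estimates agree in sign and the
IVW-RE interval excludes the null, or when all five are individually null.
Egger p-values use t(J−2); IVW and weighted median use the normal.

## Clinical cohort rules

Disease progression is a relative FVC decline of at least 10% over 12
months — computed as (baseline − follow-up)/baseline, scale-invariant,
inclusive at the boundary with a 10⁻⁹ tolerance for floating-point
representation — or death within 12 months; missing follow-up defers to an
adjudicated call when supplied. Age propensity matching fits a logistic
model of case status on age and matches greedily without replacement on
the linear predictor, cases in descending propensity order; with one
covariate this reduces to nearest-age matching, which the tests assert.
Group comparisons delegate to the standard tests (Wilcoxon rank-sum,
Kruskal–Wallis, Fisher's exact) and correlations to tie-corrected Spearman
rank correlation; these wrappers exist so every reported table carries its
group sizes and is auditable, not to re-derive the statistics.

## What the generators emulate

Every generator is a pure function of its arguments and a mandatory seed,
and returns ground truth beside the data.

* **Depth cohorts** — per-sample autosomal depth with lognormal jitter
  (CV 0.1) around 20×; aligned bases over a region set are Poisson, so
  region means carry counting noise; MSY depth expectation is
  $0.5\,m\,(1-f)\,D$. Default $m = 0.75$ puts the no-loss copy number at
  0.375, the scale observed in population controls. Region lengths are
  reduced to 1 Mb (MSY) and 20 Mb (autosomes): counting noise at these
  lengths is already far below biological variation, and recovery
  tolerances are met with two orders of magnitude to spare.
* **Single-cell cohorts** — per-cell true loss is Bernoulli on a logit
  scale (control rate 0.2, disease shift 0.7 log-odds, optional
  region-by-cell-type shift for the paired design); autosomal counts are
  Poisson(2000) and retained-Y chrY counts Poisson(λ_y = 3), so technical
  zeros follow the zero-inflation law above. Overdispersion, ambient
  RNA, doublets and cell-type-dependent depth are not modelled: passing
  tests show the calling and association logic is correct under the
  stated count model, not that real tissue meets that model.
* **GWAS pairs** — true exposure effects are shifted-exponential
  (0.02 + Exp(mean 0.06)): many instruments near the significance floor
  and a heavy tail of strong ones, the canonical GWAS effect-size shape —
  and the spread is precisely what powers the Egger intercept. Standard
  errors derive from allele frequency and sample size
  (2×10⁵ exposure / 2.5×10⁴ outcome, the scale of the relevant GWAS).
  An invalid fraction receives pleiotropic intercepts in units of the
  outcome SE: mean-zero (balanced) or N(10, 1) (directional — effects
  around ten SEs, the outlier regime the removal estimators target).
  LD is identity or simple blocks; realistic reference-panel LD is out
  of scope.
* **Clinical tables** — a Gaussian copula hits Spearman targets
  (age −0.24, telomere +0.2, lung function 0 against copy number, the
  observed cohort pattern) with margins at cohort scale (age 70.6 ± 8.3;
  copy number 0.312 ± 0.0555, placing the mean-minus-SD threshold near
  0.2565); FVC decline N(0.08, 0.10) plus a 5% death rate yields roughly
  45% progression; survival is independent of mLOY by default.

## Numerical choices and limitations

Ties in clumping are broken by SNP id after p-value, making selection
deterministic. The lasso coordinate descent iterates to 10⁻¹² on a
60-point λ path with warm starts; the brute-force profile check in the
tests agrees to 10⁻⁶. Bootstrap and simulation stages take explicit seeds
and are bit-reproducible; the pipeline derives per-stage streams from one
master seed. Degenerate inputs error early with named messages: zero
denominator depth (a failed or female sample, not mLOY), mixed dialects,
conflicting subject disease labels, exposure effects of zero in a Wald
ratio, fewer instruments than an estimator supports.

Problem sizes in the test-suite and acceptance computations — 200-sample
depth cohorts, 5,000-cell single-cell checks, 1,000 calibration
replicates at J = 50, 200 robustness replicates at J = 100, 20 end-to-end
suite replicates — were chosen as the smallest sizes at which the asserted
properties are statistically sharp. Stochastic acceptance checks assert
majorities or rates over seeded replicates rather than single-seed
events, so a pass reflects the property, not one lucky draw; the
retained-set heterogeneity check uses the median across replicates
because per-replicate I² is a max(0, ·) statistic whose mean is inflated
by χ² fluctuation even under perfect outlier removal.

The package does not compute GAP or CPI from raw physiology, fit survival
or differential-expression models (it emits analysis-ready tables and
group assignments), detect female samples, call X-chromosome mosaicism,
or correct cross-platform depth batch effects — the copy-number contrast
between cohorts sequenced differently remains confounded by platform, as
the bulk dialect documentation notes.
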