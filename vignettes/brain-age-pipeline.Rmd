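---
title: "Methods: the brain-age-gap pipeline"
author: "bagpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the brain-age-gap pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the pipeline estimates

The brain-age difference (often written $\delta$) is the gap between the
age a model predicts from a structural brain image and the person's
chronological age. Trained on a healthy reference population, a positive
$\delta$ reads as "this brain looks older than its owner", and the
question of scientific interest is whether $\delta$ tracks disease,
disease risk and function. `bagpipe` implements the full chain of that
analysis at desk scale:

1. a **residual 3D CNN** regressing age on a single-channel volume,
2. a **linear bias correction** for the regression-to-the-mean age bias,
3. **cross-subject permutation importance** over atlas regions,
4. a **phenome-wide association scan** (PheWAS) of traits against
   $\delta$ with Bonferroni and Benjamini–Hochberg control, and
5. **two-sample Mendelian randomisation** (IVW, MR-Egger, weighted
   median, Cochran's Q) from GWAS summary statistics.

Because real biobank imaging is access-controlled, the package ships a
synthetic-cohort generator that plants known age signal, known
trait–$\delta$ links, and known causal effects, so that every stage is
verified by parameter recovery rather than by fixtures copied from
elsewhere. Every function that draws random numbers takes an explicit
seed and restores the caller's RNG state; no stage uses global RNG
state.

## The synthetic cohort

`generate_atlas()` partitions an ellipsoidal "brain" mask on an
arbitrary grid into contiguous regions by nearest-seed (Voronoi)
assignment from randomly placed seed voxels. Any disjoint partition
satisfies the downstream contracts; Voronoi growth merely guarantees
contiguous, non-empty regions, standing in for an anatomical
parcellation (the real analysis uses 139 named regions; desk runs use
20).

`generate_volumes()` gives each region a fixed baseline intensity and
shifts the mean of the designated *signal regions* linearly with the
subject's apparent age:

$$\text{voxel} = \text{base}_r + \mathbb{1}[r \in \text{signal}] \cdot
  \beta_{\text{eff}} \,(\text{age} + \delta_{\text{true}} - \bar a)
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2).$$

The defaults are the package's standard study conditions: ages uniform
on 45–80 years, effect size $\beta_{\text{eff}} = 0.2$ intensity units
per year, voxel noise $\sigma = 1$, and a planted per-subject gap
$\delta_{\text{true}} \sim N(0, 3.72^2)$ years, the spread reported for
real general-population cohorts. A linear region-mean shift is
deliberately the *simplest* mechanism that both a 3D CNN and a
voxel-regression oracle can detect, which is what makes closed-form
recovery checks possible. The generator does **not** attempt realistic
neuroanatomy, tissue classes, scanner noise spectra, motion artefacts or
non-linear ageing trajectories; passing tests therefore demonstrate
that the machinery recovers planted truth under its stated model, not
that the CNN would reach any particular accuracy on real MRI.

Because $\delta_{\text{true}}$ enters the image exactly as extra
apparent age, a subject with a positive planted gap genuinely "looks
older", giving trait associations a ground truth that does not depend
on model error. `generate_traits()` links traits to the standardized
gap $z = \delta_{\text{true}} / \mathrm{sd}(\delta_{\text{true}})$:
continuous traits as $\text{baseline} + \beta z + N(0, \sigma_t^2)$,
binary traits by a logistic model with log-odds $\beta$ per SD around a
requested prevalence, ordinal traits by a proportional-odds latent
draw. Missingness is completely at random; the real pipeline simply
excludes missing rows per trait, so nothing more elaborate is modelled.

`generate_mr_summary()` draws positive instrument strengths
$\gamma_j$, then exposure effects $\gamma_j + N(0, se_x)$ and outcome
effects $\theta\gamma_j + \alpha_j + N(0, se_y)$, where $\alpha_j$ is
zero for valid instruments and follows the configured pleiotropy
distribution for the invalid fraction. A configurable share of outcome
rows is emitted in the opposite allele orientation so harmonisation has
real work to do. Only summary statistics are simulated — matching the
two-sample design — never individual-level genotypes.

## The age model

The network is a parameterised 3D ResNet: a stride-2 stem convolution
(3×3×3) into `channels[1]`, one stage per entry of `channels` with a
stride-2 downsampling convolution between stages, `n_residual_blocks`
identity blocks (conv–BN–ReLU–conv–BN plus skip, then ReLU) per stage,
global average pooling, and a linear head. Training minimises mean
squared error with Adam (fixed learning rate, default $10^{-3}$;
moments 0.9/0.999). The best-validation-MAE parameters are retained.
All convolution is implemented as im2col gathers feeding BLAS matrix
products, with the backward scatter as a cached sparse matrix product —
the whole network is plain R linear algebra, verified against numerical
gradients in the test suite.

Choices worth knowing about:

* **Stride-2 stem.** Full-resolution residual stages dominate compute
  for no accuracy gain at these signal strengths; halving resolution at
  the stem is the standard ResNet trick and keeps a 32³ cohort
  trainable on one CPU core in minutes.
* **Per-stage depth.** `n_residual_blocks` accepts a vector such as
  `c(0, 1, 1)`, leaving the widest stage shallow. The default used
  throughout the tests is channels `c(4, 8, 16)` with depths
  `c(0, 1, 1)` — roughly 13k parameters, which is ample for the planted
  linear signal.
* **Input normalisation.** Each volume is z-scored before the stem
  (`normalize = TRUE`); disable it to feed raw intensities.
* **Head anchoring.** On the first training call the head intercept is
  anchored at the mean training age, so optimisation starts from the
  constant-mean predictor and any improvement is signal learned.
* **Degenerate inputs.** Training aborts with a diagnostic on a
  non-finite loss; batch normalisation skips one-subject tail batches;
  an input shape smaller than the total downsampling factor
  ($2^{\#\text{stages}}$) is rejected at configuration time.

The real analysis this mirrors ran at 182×218×182 on GPUs; the code
accepts that shape, but the package makes no claim of reproducing real
MRI accuracy figures, which require the original access-controlled
cohort.

## Bias correction

Deep age regressors under-predict old subjects and over-predict young
ones (regression to the mean). The correction fits
$\hat y_{\text{raw}} = \alpha + \beta\,\text{age}$ by ordinary least
squares *on the training split only* and then, by default, inverts:
$\hat y = (\hat y_{\text{raw}} - \alpha)/\beta$. Inversion makes a
perfect-after-correction predictor exactly unbiased, which is why it is
the default; the alternative convention of subtracting the fitted
residual trend is available as `method = "residual"`. Fitting on the
training split and applying everywhere else is a leakage guard; the
test suite verifies that the post-correction slope of $\delta$ on age
is null on independent data. $\delta$ is always
`corrected_pred - age`, an exact identity on every record.

## Permutation importance

A region's importance is the rise in cohort MAE after exchanging that
region's voxels between subjects — a cross-subject patch exchange at
fixed coordinates, valid because all volumes share one template grid.
Within-subject shuffling is deliberately rejected: it would destroy
intensity statistics that cross-subject exchange preserves (the
multiset of region patches is conserved, which the tests check
exactly). Permutations are uniform bijections excluding the identity
(the identity destroys no information); `n_repeats` defaults to 10 and
the per-repeat values are averaged. Sampling noise can make a
non-informative region's value slightly negative; values are reported
as computed, never clamped. `rank_regions()` flags regions whose
permutation raises MAE by more than 0.10 years — a reporting threshold,
not an inference rule — breaking ties by ascending region id.

## The phenome scan

`association_scan()` standardizes the exposure to SD units using the
analysis cohort's $\delta$ SD, then fits one model per declared trait
with age, sex and assessment centre as fixed-effect covariates: `lm`
for continuous traits (optionally rank-based inverse-normal
transformed; untransformed is the default since conventions differ),
logistic `glm` for binary traits (reported as OR per SD), and a
cumulative-logit `MASS::polr` for ordinal traits (also OR per SD — the
proportional-odds treatment is this package's explicit choice for
ordered traits). Traits failing preconditions (too few non-missing
rows, a class with fewer than two members, fewer than three observed
ordinal levels) are reported as skipped with a reason; non-converged or
separated logistic fits are flagged, never imputed — an agnostic scan
must surface its failures. `n_used + n_missing` equals the cohort size
exactly, per trait.

Multiplicity control is classical: `bonferroni_threshold()` is
$\alpha/m$ with $m$ an explicit argument (published thresholds
sometimes reflect a different effective test count than the headline
trait count, so the divisor is never guessed), and `bh_fdr()` is the
Benjamini–Hochberg step-up rule, implemented through `p.adjust` and
cross-checked in the tests against a hand enumeration.

## Mendelian randomisation

`harmonise()` aligns outcome to exposure effect alleles, flipping betas
and complementing allele frequencies where orientations differ, and
drops palindromic (A/T, C/G) variants by default; with
`palindromic = "infer"` they are retained when both allele frequencies
are informative (|eaf − 0.5| > 0.08, a common operational cutoff).
Every flip and drop is written to an audit table. `ld_clump()` prunes
by the greedy rule — keep the smallest exposure p, drop everything with
r² ≥ 0.1 (default) against it — on a user-supplied r² matrix, so no
reference genotype panel is needed.

The estimators follow the standard two-sample formulations:

* **IVW**: weighted regression of outcome on exposure betas through the
  origin with weights $1/se_y^2$, fixed-effect standard error
  $1/\sqrt{\sum \beta_x^2/se_y^2}$, normal p-values.
* **MR-Egger**: weighted least squares *with* intercept after orienting
  all $\beta_x \ge 0$; the intercept estimates average directional
  pleiotropy and carries its own t test (df $n-2$). Standard errors use
  the weighted residual variance, i.e. the multiplicative
  random-effects convention of `lm(…, weights = )`.
* **Weighted median**: per-variant Wald ratios weighted by first-order
  delta-method inverse variance ($se = se_y/|\beta_x|$; the
  second-order term is omitted as it matters only for weak
  instruments), interpolated at cumulative weight 0.5; the standard
  error comes from a seeded 1,000-draw parametric bootstrap.
* **Cochran's Q** is attached with df $n-1$ (IVW) or $n-2$ (Egger), and
  both the statistic and its chi-square p-value are reported, so either
  reading of a published "Q" figure can be compared.

`mr_suite()` chains harmonisation, optional clumping and all three
estimators, flags pleiotropy (Egger intercept p < 0.05) and
heterogeneity (any Q p < 0.05), and degrades gracefully to IVW plus
median when fewer than three variants survive.

## Problem sizes and test design

The test and acceptance runs use sizes chosen so the whole suite
completes comfortably on a single CPU while keeping every statistical
check well-powered: the standard training cohort is 32³ voxels with 400
subjects (300/50/50 split); the importance-recovery study repeats the
*entire* pipeline — fresh cohort, fresh training, fresh scan — twenty
times at 16³ with 20 regions and 2 planted signal regions (the two
largest regions of the atlas: both signal regions carry the *same*
apparent-age signal, so a model that has read a large signal region can
rationally ignore a very small second one — planting in comparable,
well-sized regions keeps the recovery question about the scan rather
than about feature redundancy); the PheWAS
calibration uses 1,000 null traits over 20 replicates and 100-replicate
coverage checks at n = 5,000 for the planted odds ratios (1.42 and
2.39 per SD, with prevalences 5% and 2% giving realistic case counts);
the MR checks use 200-replicate Monte Carlo at 30 instruments.

Two test-design points deserve a note. First, the bias-removal check
fits the correction on a training split of 2,000 and tests the residual
delta-on-age slope on a validation split of 100: under the inversion
form, estimation noise in $\hat\beta$ induces a *true* residual slope
whose size relative to the validation test SE is
$\sqrt{n_{\text{val}}/n_{\text{train}}}$, so a near-nominal
non-significance rate requires the training split to dwarf the
validation split — exactly the regime of real cohorts, where the
correction is fitted on thousands. Second, the
weighted-median unbiasedness check uses balanced (mean-zero)
pleiotropy, which is the regime in which the estimator is actually
unbiased at finite instrument count; under directional pleiotropy it is
merely *less* biased than IVW, and that ordering is what the tests
assert.

## Known limitations

* The synthetic generator's linear region-mean signal is much easier
  than real ageing anatomy; CNN accuracy numbers on it say nothing
  about accuracy on real MRI.
* The healthy/unhealthy stratification of real cohorts involves
  clinical coding logic; the simulator exposes only a binary healthy
  flag.
* Ordinal traits use proportional odds throughout; scans built on other
  ordered-response conventions will differ.
* LD clumping requires the caller to supply the r² matrix; there is no
  reference-panel lookup.
* MR covers IVW, Egger and weighted median only — no multivariable MR,
  no outlier-removal variants.
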