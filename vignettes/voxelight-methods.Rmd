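---
title: "Searchlight morphometry and longitudinal decline mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight morphometry and longitudinal decline mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelight)
```

## The scientific problem

`voxelight` implements a statistical pipeline for asking, in an aging cohort,
whether a binary exposure — here the *digital divide*: regular use versus
non-use of computers and mobile devices in later life — leaves a footprint in
brain structure, whether that footprint carries information about cognition,
and whether the exposure changes the *rate* at which gray matter is lost over
time. The same machinery applies to any binary exposure measured alongside
voxel-wise gray-matter volume (GMV) maps, cognitive test batteries, and a
follow-up scan.

The pipeline chains seven stages:

1. **Cohort construction** — exposure groups from a single frequency item;
   propensity-score matching on demographics and comorbidities.
2. **Cognitive composites** — per-domain weighted sums of standardized test
   scores, the weights estimated as one-factor loadings.
3. **Voxel-wise morphometry** — covariate-adjusted two-group *t* maps over a
   group brain mask, Benjamini–Hochberg FDR, connected-cluster extraction,
   Cohen's *d* effect sizes.
4. **Searchlight classification** — at each voxel, PCA features of a small
   spherical neighborhood feed a cross-validated linear SVM; the held-out
   accuracy becomes a map; significant voxels that also classify above
   threshold form the *constrained regions*.
5. **Cognitive representation** — at each constrained voxel, a linear model
   predicts each cognitive composite from the searchlight features; the
   predicted-vs-observed correlation is tested against a permutation null
   with per-domain FDR.
6. **Longitudinal rates** — per-subject annual GMV decline-rate maps from two
   timepoints, atlas-level aggregation, covariate-adjusted group contrasts,
   and rate–cognition correlations.
7. **Growth and mediation models** — a two-level mixed model of cognitive
   trajectories with exposure moderating the slope, and product-of-coefficients
   mediation of cognitive change through regional decline rates.

Because studies of this design rarely deposit their imaging data, the package
ships a synthetic cohort generator with planted ground truth, so every stage
has a recovery test and the whole pipeline can be exercised end to end at
desk scale.

## Group assignment and matching

Exposure is read off a single 0–5 frequency item ("How often do you use a
computer and mobile devices?"): 0–2 maps to the low-use (DD) group, 4–5 to
the regular-use (ODD) group, and 3 is left unassigned because the
classification rule covers only the two poles of use. `assign_group()` is a
pure function of the item.

Matching follows the most common published propensity-score recipe; since
reports of this design typically state only that "PSM was used", every choice
is explicit and configurable:

* logistic regression of exposure on age, gender, education, and comorbidity
  flags (`fit_propensity()`), with a ridge-penalized IRLS fallback when the
  groups are separable;
* greedy 1:1 nearest-neighbor matching without replacement on the logit of
  the score, within a caliper of 0.2 SD of the logit (`match_pairs()`); the
  processing order is a fixed shuffle under the supplied seed so ties resolve
  deterministically;
* standardized-mean-difference balance diagnostics before and after
  (`balance_table()`).

Greedy matching is order-dependent and not globally optimal; on
well-separated score configurations it coincides with the exhaustive optimum,
which is what the tests verify.

## Cognitive composites

Each cognitive domain (memory, visual-spatial, processing speed, executive
function, working memory, language) is summarized by a weighted sum of the
standardized scores of its tests, re-scaled to mean 0, SD 1 across subjects.
The weights are estimated per domain as single-factor maximum-likelihood
loadings (`factanal`), falling back to first-principal-component loadings
when the ML fit is unavailable (e.g. with exactly two tests, where the
one-factor model is just-identified only with constraints). A single-test
domain — language, carried by the verbal fluency test alone — uses the test's
z-score directly. A full multi-domain confirmatory factor model with
cross-loadings would require committing to a path diagram for the whole
battery; independent per-domain one-factor weights preserve the mechanism
(path coefficients as weights) without guessing that structure. Externally estimated weights can be supplied.

## Voxel-wise morphometry

The brain mask contains the voxels whose across-subject mean GMV exceeds 0.2
(`build_mask()`), the standard threshold on the mean gray-matter map.
`group_tmap()` fits, at every in-mask voxel, the linear model

$$\mathrm{GMV}_v = \beta_0 + \beta_1\,\mathrm{group} + \gamma^\top
\mathrm{covariates} + \varepsilon$$

and reports the *t* statistic of the group indicator (exposed minus control)
with two-sided *p* on $n - \mathrm{rank}(X)$ degrees of freedom. Covariates
(age, gender, education, total intracranial volume) are adjusted inside the
voxel model, not by pre-residualization — the two differ in degrees of
freedom and in how covariate-group collinearity is handled. Multiplicity is
controlled with Benjamini–Hochberg FDR at 0.05, two-sided; clusters are
face-connected (6-connectivity) components of the significance mask with a
10-voxel minimum extent, each reporting its peak |t| voxel in 0-based voxel
indices and millimetres. Published analyses of this kind often quote separate
voxel-level and cluster-level thresholds (e.g. 0.05 and 0.001) without
stating which of the two forms clusters and which declares them; both numbers
are plain arguments here and no interpretation is baked in.

## The searchlight stage

At each in-mask voxel, the neighborhood is the set of in-mask voxels whose
centers lie within `radius_mm` (default 2 mm) of it. On the default 1.5 mm
isotropic grid that radius yields 7-voxel spheres — the center plus its six
face neighbors at 1.5 mm, edge neighbors at 2.12 mm being outside — which is
the geometry implied by combining a 2 mm radius with 1.5 mm voxels.
Neighborhoods are clipped at the mask boundary and their sizes recorded.

The subjects-by-neighborhood matrix is centered (not scaled — voxels share
units) and decomposed; the smallest number of principal components reaching
80% cumulative variance is retained. A linear soft-margin SVM with
regularization constant 1 is then scored by stratified 10-fold
cross-validation, and the pooled held-out accuracy (every subject classified
exactly once) is written to the center voxel. Pooled accuracy is preferred to
per-fold averaging for stability at small *n*; the fold assignment is drawn
once per map from the spec seed, so maps are deterministic and voxels are
compared on identical folds.

By default PCA is fit inside each training fold and applied to its test fold,
so no test information leaks into the features. The variant in which PCA is
fit once on all subjects before classification — the order many published
searchlight diagrams depict — is available as
`pca_per_fold = FALSE` for sensitivity analyses; with 80 subjects and 7-voxel
spheres the two differ by well under the map's sampling noise. Features are
computed from covariate-unadjusted volumes — adjustment enters only the
*t*-map stage — with pre-residualization left to the caller if wanted.

**Constrained regions** are the FDR-significant voxels whose accuracy
strictly exceeds the threshold (default 0.6); the remaining significant
voxels are *excluded*. The two sets partition the significance mask exactly.
Because the partition is defined inside the significant mask, the package
computes accuracies only where they are needed when given `voxels =
which(significant)` — the full map is available but not required.

A calibration fact worth knowing: under the null, pooled 10-fold CV accuracy
at $n = 80$ has mean 0.5 but standard deviation ≈ 0.077, noticeably wider
than the binomial $\sqrt{0.25/80} = 0.056$, because held-out predictions
share training data across folds. The probability of a null voxel exceeding
0.6 is therefore ≈ 5%, not the ≈ 3% a binomial intuition suggests; the 0.6
threshold is a heuristic screen, not a significance test.

## Cognitive representation

At each constrained voxel, the searchlight features predict each composite
with ordinary least squares. Predictions are out-of-fold by default: the
in-sample predicted-vs-observed correlation of a fitted linear model is
optimistically biased by construction (it equals the multiple correlation),
while held-out predictions measure generalization. The literal in-sample
variant is available (`insample = TRUE`).

The observed correlation between predictions and scores is referred to a
permutation null: the predicted vector is shuffled, the correlation
recomputed `n_perm` times (default 10,000), and
the two-sided add-one p-value $(1 + \#\{|r_\pi| \ge |r|\})/(n_{\mathrm{perm}}
+ 1)$ reported. For $n \le 8$ an exhaustive enumeration over all $n!$
permutations is available and is used by the tests as an exactness check.
FDR is applied per domain across constrained voxels at 0.001, matching
per-domain reporting; `domain_coverage()` gives the fraction of constrained
voxels significant per domain and `contrast_domains()` the set differences.

One honest caveat, verified by simulation in the test suite: out-of-fold
predictions are *negatively* correlated with the outcome under the null
(mean $r \approx -1/\sqrt{n_{\mathrm{train}}}$, the fold-mean artifact),
while the shuffle null is centered at zero. The two-sided test absorbs most
of this offset at the default settings, but p-values at very small *n* are
mildly anticonservative; the in-sample variant has the opposite and larger
(optimistic) mismatch. This is a property of pairing cross-validated
predictions with a permutation null, not of the implementation.

## Longitudinal modelling

With exactly two scans, the annual decline rate at voxel $v$ for subject $i$
is

$$r_{iv} = \frac{V_{iv}(t_2) - V_{iv}(t_1)}{V_{iv}(t_1)\,\Delta t_i},$$

a signed fraction of baseline per year (negative = atrophy); an
absolute-difference mode $(V_2 - V_1)/\Delta t$ is available. The convention
is stated explicitly wherever rates are printed because "decline rate" is
sign-ambiguous in prose. Zero-baseline voxels are undefined in fractional
mode, masked out, and counted. The computation is closed-form, so recovery
of the generator's planted rates is machine-precision — a test, not a
tolerance. Rates aggregate to atlas regions by in-mask means; group
contrasts on rate maps reuse the voxel-wise linear model with baseline
covariates; region rates correlate with annualized composite change
(follow-up minus baseline over $\Delta t$) by Pearson's method.

**Mediation.** Whether exposure's effect on cognitive change runs through a
regional decline rate is estimated by product of coefficients: $a$ from
exposure to rate, $b$ from rate to change adjusting for exposure, total $c$,
and proportion mediated $ab/c$, all covariate-adjusted, with percentile
bootstrap intervals over subjects (default 5,000 draws). The proportion is
reported as undefined when $ab$ and $c$ disagree in sign or $|c|$ is
negligible — in those regimes the ratio is not interpretable. The proportion
is invariant to affine rescaling of the outcome, which the tests check. The
estimator is a documented standard recipe; reports of this design typically
state only the headline percentage.

**Growth model.** Cognitive trajectories follow the two-level model

$$\text{score}_{ij} = \pi_{0i} + \pi_{1i}\,\mathrm{time}_{ij} + e_{ij},$$
$$\pi_{0i} = \beta_{00} + \beta_{01}\,\mathrm{age}_i + \beta_{02}\,\mathrm{gender}_i + \beta_{03}\,\mathrm{edu}_i + \beta_{04}\,\mathrm{group}_i + r_{0i},$$
$$\pi_{1i} = \beta_{10} + \beta_{11}\,\mathrm{age}_i + \beta_{12}\,\mathrm{gender}_i + \beta_{13}\,\mathrm{edu}_i + \beta_{14}\,\mathrm{group}_i + r_{1i},$$

fitted as a single mixed model by maximum likelihood (`lme4`), with
correlated random intercepts and slopes. $\beta_{14}$ — the exposure effect
on the annual slope — is the quantity of interest. The intercept-only null
model (`fit_null_model()`) reports the ICC that justifies the hierarchical
structure. Singular fits (a variance component at the boundary, common when
the true random-slope variance is near zero with three visits) are flagged,
never silently accepted; fixed effects remain consistent in that regime.

## The synthetic cohort generator

The generator is the package's study design. Its defaults emulate the
conditions the pipeline targets, scaled to a desk:

* **Grid** 24³ voxels at 1.5 mm isotropic (the framework is grid-agnostic;
  tests use 10–16³ where the property is size-free). A fixed radial base
  pattern (plateau 0.45, smoothly falling to 0) stands in for cortex so that
  the 0.2 mean-GMV threshold produces a brain-like mask.
* **Noise** per subject: a Gaussian field (SD 0.1) smoothed with an 8 mm
  FWHM kernel, the conventional VBM smoothing, applied by the generator
  because acquisition preprocessing is out of scope.
* **Planted effects**: inside each configured sphere, exposed-group voxels
  are shifted by $d$ times the empirical pooled voxel SD, so the planted
  standardized effect equals $d$ by construction (the calibration test
  checks $|\hat d - d| < 0.15$ at $n = 200$/group).
* **Demographics**: the exposed group is drawn 3 years older pre-matching —
  the one injected imbalance, so matching diagnostics have a known
  direction; other covariates are balanced.
* **Cognition**: domain scores are weighted regional mean GMV (z-scaled)
  plus Gaussian noise; raw tests load on each domain's score with loadings
  0.9, 0.7, … so the composite stage has a recoverable factor structure.
* **Follow-up**: $V_{t2} = V_{t1}(1 + \mathrm{rate}\,\Delta t)$,
  multiplicative so moderate rates keep volumes non-negative and "percent
  per year" is natural. The rate is the base rate (−0.005/yr) plus the
  exposure-by-region delta (−0.01/yr), plus two variability terms: a
  per-subject deviation (SD 0.004/yr, shared across voxels — individual
  aging speed) and a spatially smooth within-subject field (SD 0.004/yr).
  Without these the planted rates would be deterministic, within-group rate
  variance would be exactly zero, and any group contrast on rates would be
  degenerate; real cohorts never behave that way. The realized rates are
  returned as ground truth, so exact recovery remains testable. Intervals
  are 3.2 ± 0.3 years.

What the generator does **not** emulate: cortical anatomy and folding,
scanner artifacts and site effects, registration error, non-Gaussian
pathology, missingness mechanisms, or practice effects on cognition. Tests
passing on these phantoms certify the statistical machinery — calibration
under the null, recovery of planted effects at the configured sizes — not
performance on real MRI, where registration and segmentation error dominate.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; every stochastic function
  restores the caller's RNG state. Identical config + seed reproduces
  volumes and maps bit-for-bit.
* Voxel indices are 0-based in reports; mm coordinates come from the
  isotropic affine; peaks are reported in both.
* Zero-variance neighborhoods yield a flagged zero feature and fall back to
  majority-class prediction rather than aborting a map; a failed voxel never
  kills the stage.
* Perfect separation in the propensity model switches to a ridge-penalized
  IRLS fit (λ = 0.01) with a warning — scores stay inside (0, 1).
* Zero pooled SD makes an SMD 0 with a warning; empty masks, empty match
  sets, and rank-deficient designs are hard errors naming the offender.
* Exact ties at the accuracy threshold are excluded from constrained regions
  (strict inequality, as "greater than" demands).

## Problem sizes used by the checks

The acceptance checks run, per invocation: one planted-recovery cohort (24³,
160 subjects, d = 1.2), ten null cohorts (16³, 80 subjects each), 200
permutation-null voxels at 500 permutations, 100–200 growth-model replicates
(200 subjects × 3 visits), and a 500-subject mediation with a 500–1,000-draw
bootstrap — sizes at which every targeted property is measurable with
comfortable Monte-Carlo margins on a single CPU.

## Known limitations

* Greedy caliper matching is not optimal matching; IPTW, full matching, and
  matching with replacement are out of scope.
* The cluster stage does no random-field or permutation cluster inference;
  clusters describe, FDR decides.
* The permutation null treats predictions as exchangeable with the observed
  scores; with cross-validated predictions this is approximate (see the
  representation section).
* Exactly two timepoints are assumed for rates; more visits would need
  per-subject least-squares slopes, a documented extension.
* The growth model fixes the level-1 trajectory to be linear in time.
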