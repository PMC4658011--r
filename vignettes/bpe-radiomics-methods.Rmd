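---
title: "Methods: tumor and BPE radiomics on DCE-MRI"
author: "radbpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor and BPE radiomics on DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radbpe implements a radiomic analysis for discriminating triple-negative
(TN) breast cancer from other molecular subtypes on 4-timepoint dynamic
contrast-enhanced MRI (DCE-MRI). Its distinctive scientific premise is that
the *background parenchymal enhancement* (BPE) of the fibroglandular tissue
surrounding a tumor carries subtype information of its own: spatial
heterogeneity of parenchymal enhancement, quantified by 3-D texture
statistics, is associated with TN status over and above what tumor features
provide. This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic data do and do not establish.

## The pipeline

1. **Segmentation.** The breast is contoured on the t3 frame (all tissues
   near maximal intensity) by skin-edge thresholding, chest-wall removal,
   largest 26-connected component and a 3×3×3 morphological closing. The
   tumor is grown from a seed voxel as the maximal 26-connected region
   within a gray-level band. Remaining breast tissue is split into
   fibroglandular parenchyma and adipose tissue by two-class fuzzy c-means
   on the *pre-contrast* (t1) intensities. Volumetric breast density is the
   parenchymal voxel fraction of the breast, in percent.
2. **Kinetics.** Per voxel, with `S1..S4` the signal at the four timepoints
   (0, 1, 2, 6 minutes) and `Smax` the post-contrast maximum over t2–t4
   attained at `tmax`: rate-in `(Smax−S1)/tmax` (signal/min), percent
   enhancement `PE = 100 (Smax−S1)/S1`, and signal enhancement ratio
   `SER = (Smax−S1)/(S4−S1)` (SER = 1 for a late peak, > 1 for washout).
3. **Texture.** Each map, restricted to a compartment, yields 4 first-order
   statistics (mean, SD, Fisher skewness, excess kurtosis) and, after
   8-level quantization, 9 gray-level co-occurrence (GLCM) statistics
   averaged over the 26 directions of 3-D space at a 1-voxel offset —
   13 × 3 maps = 39 features per compartment. Parenchymal features are the
   BPE textures.
4. **Supervised modeling.** Linear SVM under 10 repetitions of stratified
   10-fold cross-validation. Within every training fold only: features are
   ranked by the χ² statistic on 10 equal-frequency bins, the top 30 enter
   sequential forward floating selection (SFFS) whose criterion is the mean
   held-out AUC of the SVM under internal stratified 5-fold CV, and the
   final SVM is fitted on the selected subset. Held-out folds are scored by
   decision sign (accuracy, sensitivity, specificity) and decision value
   (AUC). Summaries are means over all repetition × fold values with
   percentile 95% intervals over the 10 repetition means. Models on the
   same partitions are compared by a paired two-sided Wilcoxon signed-rank
   test over the repetition × fold values.
5. **Unsupervised analysis.** BPE textures are z-scored across cases
   (sample SD) and split into two partitions by Euclidean k-means
   (k-means++ seeding, Lloyd iterations, best inertia of 50 restarts); the
   TN composition of the TN-enriched partition is reported with a
   descriptive Fisher exact p.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| acquisition times | 0, 1, 2, 6 min | pre-contrast, two early frames, one late frame; fixes the rate-in denominator |
| `baseline_floor`, `denom_floor` | 1 signal unit | voxels with near-zero PE/SER denominators are flagged invalid and excluded from texture statistics, never imputed |
| gray levels `G` | 8 (3-bit) | coarse quantization keeps the 8×8 co-occurrence table well populated in small compartments and absorbs any increasing affine rescaling of a map |
| FCM fuzzifier `m`, `tol`, `max_iter` | 2, 1e-5, 300 | standard fuzzy c-means settings; convergence on maximal centroid change |
| `parenchyma_is` | `"brighter"` | on fat-suppressed T1-weighted images fibroglandular tissue is typically brighter than suppressed fat at t1; configurable because acquisition conventions vary |
| `rank_keep` | 30 | enough headroom above the subset cap for the wrapper to move in |
| `sffs_max_size` | 10 | "a small subset" — the wrapper almost always stops earlier via its no-improvement rule |
| SVM cost `C` | 1 | plain regularized linear SVM; AUC from raw decision values, no probability calibration |
| k-means restarts | 50 | inertia landscape with 39 z-scored columns and n ≈ 88 has local optima; 50 k-means++ starts make the best-inertia solution stable |

## Numerical and convention choices

- **"Maximum" excludes the baseline.** `Smax` is the maximum of t2–t4, so
  flat or decreasing courses give PE ≤ 0 and a negative rate-in instead of
  0/0. Ties take the earliest frame.
- **Rate-in is time-normalized** (signal/min). The unnormalized difference
  would duplicate PE's numerator; division by minutes-to-peak is what makes
  it a distinct kinetic feature.
- **GLCM formulas** (natural-log entropy): energy Σp², contrast Σ|i−j|p
  (dissimilarity form), correlation Σ(i−μx)(j−μy)p/(σxσy) (0 when a
  marginal is degenerate), variance Σ(i−μ)²p with μ = (μx+μy)/2,
  homogeneity Σp/(1+|i−j|), sum mean ½Σ(i+j)p, entropy −Σp ln p, inertia
  Σ(i−j)²p, cluster shade Σ(i+j−μx−μy)³p. Classic "contrast" and "inertia"
  coincide; to keep nine distinct features, contrast is the
  absolute-difference form and inertia the squared-difference form — both
  are exported and the naming is flagged here deliberately.
- **Direction handling.** Pair counts are not symmetrized; averaging over
  all 26 directions covers both orientations of each axis (the GLCM of −d
  is the transpose of that of d, and all nine statistics are
  transpose-invariant). Directions with no valid pair are dropped from the
  average, not counted as zero.
- **Quantization is per-region** (min/max within the compartment mask),
  matching single-compartment extraction; the in-mask maximum maps to
  G−1. A constant region quantizes to level 0 and is flagged; its GLCM
  signature is energy 1, entropy 0, contrast = inertia = 0, homogeneity 1.
- **Skin threshold.** `auto` is Otsu's criterion in its three-class
  (two-threshold) form, taking the *lower* threshold. A t3 frame is at
  least trimodal — air, suppressed fat, enhancing tissue — and the
  two-class method can split fat from gland instead of air from tissue;
  the lowest split of the three-class partition is the skin edge.
- **Degenerate inputs** raise typed errors rather than silently producing
  numbers: empty masks, all-identical FCM intensities, single-class
  training folds, zero-variance z-score inputs, non-paired model
  comparisons.
- **Signed-rank test.** Zero differences are dropped (all-zero ⇒ p = 1).
  For ≤ 25 informative pairs the exact conditional distribution is built by
  dynamic programming over the observed doubled midranks (ties included);
  beyond that a normal approximation with tie and continuity correction is
  used.
- **Determinism.** Every stochastic stage (phantom noise, table sampling,
  partition draws, SFFS internal folds, k-means++ seeding) flows from an
  explicit seed; identical spec + seed reproduces bit-identical outputs,
  which the run manifest records.

## What the synthetic data emulate — and what they do not

Patient volumes and patient-level feature tables cannot ship with the
package, so both are emulated:

- **Phantoms** (`phantom_spec()`): a half-ellipsoid breast (flat face =
  chest wall) with a spherical tumor and a central parenchymal core built
  by ranking non-tumor breast voxels by ellipsoidal radius until a target
  volume fraction is met (ground-truth density is exact to one voxel).
  Compartments follow fixed 4-point kinetics — adipose (60, 70, 75, 72),
  parenchyma (100, 180, 200, 190), tumor (100, 250, 300, 280) in arbitrary
  units, i.e. dim barely-enhancing fat, persistent parenchymal enhancement,
  tumor washout. Parenchymal enhancement amplitude is modulated by
  `1 + field`, a Gaussian random field (white noise smoothed by a separable
  Gaussian kernel, rescaled to a target variance); the TN preset uses
  variance 0.09 vs 0.01 for non-TN with a 6 mm correlation length, encoding
  the hypothesis that TN parenchyma enhances more heterogeneously. No
  quantitative description of real BPE spatial structure exists to estimate
  these knobs from; they are conditions, not cohort estimates. The default
  grid is 48 × 48 × 28 voxels at 2 mm spacing with additive Gaussian noise
  (SD 2 signal units). There is no MR physics: no bias field, no motion,
  no partial volume beyond voxelization, no non-mass lesions.
- **Feature tables** (`feature_table_spec()`): 88 lesions with exactly 11
  TN (fixed-count mode), unit-variance Gaussian blocks with within-block
  equicorrelation 0.3 and class shifts of 1.5 SD for every BPE-texture
  column, 0.6 for tumor-texture and clinical columns, 0.3 for density.
  The BPE/tumor contrast mirrors the headline finding (BPE adds value);
  the clinical effect matches the tumor tier because clinical mass
  descriptors were top discriminators of tumor-only models. Non-TN cases
  carry subtype metadata in the cohort's proportions (45 Luminal A, 28
  Luminal B, 4 HER2-only; ER+ = the 73 luminal cases, PR+ a 63-case subset),
  so the per-subtype task filters yield realistic task sizes
  (n = 88, 84, 74, 56, 39).

Two consequences deserve emphasis. First, because the synthetic class
signal is spread *evenly* across a correlated block, sparse wrapper
selection is pessimistic relative to concentrating the same total signal
in a few strong features: a no-selection SVM on all tumor-scope columns
can outperform the fold-wise selected subsets on these tables. Passing
tests therefore establish correctness and ordering behavior (BPE scope
beats tumor scope; permutation null at chance), not the absolute AUC
levels reported for patient data. Second, the comparator subtypes share
one non-TN feature distribution, so per-subtype tasks differ only in
sample size, not in difficulty.

## The leakage canary

Both feature-selection steps run strictly inside each training fold. The
canary check permutes labels and expects held-out AUC at chance. With 11
positives among 88 cases and 84 candidate features, a *single fixed*
permutation retains sizable chance associations that legitimately persist
across folds of the same finite sample, so its conditional mean AUC varies
widely even for a leak-free pipeline. The canary therefore draws a fresh
permutation for every repetition — under label exchangeability the
expected held-out AUC is then exactly 0.5 — and averages ten of them.

## Problem sizes used by the test suite and acceptance script

Cohort analyses use the default cohort-sized table (n = 88). The primary task
(TN vs others) runs the full 10 × 10-fold protocol in both scopes; the
four per-subtype tasks use 3 repetitions, the seed-robustness check uses
10 tables at 2 repetitions, and the canary 10 single-repetition runs.
GLCM engine/oracle equivalence uses 6×6×6 volumes (100 in the suite, 20 in
the script) against a brute-force pair enumerator at 1e-10. Phantom checks
use the default 48 × 48 × 28 grid.

## Known limitations

- The imaging feature row is 79 columns (2 × 39 textures + density);
  radiologist-read clinical descriptors exist only in the synthetic tables,
  since no reader is available.
- Single-breast, mass-lesion geometry only; no bilateral handling, no
  DICOM ingestion, no nonlinear SVM kernels, no k selection beyond k = 2.
- The absolute classification metrics on synthetic tables depend on the
  chosen effect structure and are not estimates of patient-data
  performance; only their ordering and null behavior are design targets.
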