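# radbpe

Radiomics of the tumor **and** its surrounding parenchyma on dynamic
contrast-enhanced breast MRI (DCE-MRI), for discriminating triple-negative
(TN) breast cancer from other molecular subtypes.

Triple-negative cancers (ER−/PR−/HER2−) lack targeted therapies and carry
the poorest prognosis, so a non-invasive imaging signal for TN status is
clinically valuable. Most CAD work characterizes the tumor alone; the
premise here is that the *background parenchymal enhancement* (BPE) of the
fibroglandular tissue around the tumor is itself informative — TN disease
is associated with more spatially heterogeneous parenchymal enhancement.
The package is aimed at quantitative-imaging researchers who want a fully
scripted, reproducible version of this analysis: every interactive step of
the usual clinical workflow (chest-wall polygons, seed clicks, manual edits) is
an explicit argument, and a synthetic phantom/table generator stands in
for patient data so each stage is testable end to end.

## What it computes

**Segmentation.** Breast (skin-edge threshold via three-class Otsu, largest
3-D component, morphological closing, chest-wall exclusion), tumor (seeded
26-connected region growing within a gray-level band), and a fuzzy c-means
split of the remaining tissue into parenchyma and adipose fat on the
pre-contrast frame; volumetric breast density = |parenchyma| / |breast|.

**Pharmacokinetic maps.** With S₁..S₄ the signal at t₁..t₄ (0, 1, 2, 6 min)
and S\_max the post-contrast maximum attained at t\_max:

- rate-in = (S_max − S₁) / (t_max − t₁)  [signal/min]
- PE = 100 · (S_max − S₁) / S₁  [%]
- SER = (S_max − S₁) / (S₄ − S₁)  (SER = 1 late peak, > 1 washout)

**Texture.** Per map and compartment: mean, SD, Fisher skewness g₁, excess
kurtosis g₂, plus nine gray-level co-occurrence (GLCM) statistics — energy,
contrast, correlation, variance, homogeneity, sum mean, entropy, inertia,
cluster shade — computed at 1-voxel offset after 8-level quantization and
averaged over the 26 directions of 3-D space. 13 statistics × 3 maps = 39
features per compartment; the parenchymal 39 are the BPE textures.

**Supervised modeling.** Linear SVM under 10 repetitions of stratified
10-fold cross-validation with *fold-encapsulated* feature selection:
χ² ranking (10 equal-frequency bins) keeps 30 candidates, sequential
forward floating selection (SFFS, internal 5-fold CV AUC criterion) picks
the subset, all inside each training fold. Metrics: accuracy, sensitivity,
specificity at the decision boundary and AUC from decision values, with
percentile 95% CIs over repetitions; paired models are compared by a
Wilcoxon signed-rank test (exact for ≤ 25 informative pairs, ties handled).

**Unsupervised analysis.** z-scored BPE textures, two-partition Euclidean
k-means (k-means++, best of 50 restarts), TN composition of the enriched
partition with a Fisher exact p.

## Worked example

A synthetic cohort of realistic size (88 lesions, 11 TN) with the class signal
concentrated in the BPE textures:

```r
library(radbpe)
tab <- generate_feature_table(feature_table_spec(seed = 11))
cfg <- cv_config(repetitions = 2, seed = 42)

run_nested_cv(tab, cfg, scope = "tumor")
#> <cv_result> scope 'tumor', n = 88, 2 x 10-fold CV
#>   accuracy     84.9 (84.5, 85.3)
#>   sensitivity  15.0 (10.2, 19.8)
#>   specificity  94.9 (94.8, 95.0)
#>   auc          0.690 (0.632, 0.747)

r_both <- run_nested_cv(tab, cfg, scope = "tumor+bpe")
r_both
#> <cv_result> scope 'tumor+bpe', n = 88, 2 x 10-fold CV
#>   accuracy     89.9 (87.9, 91.8)
#>   sensitivity  45.0 (40.2, 49.8)
#>   specificity  96.1 (95.1, 97.1)
#>   auc          0.890 (0.859, 0.922)

head(selection_frequency(r_both), 3)
#>                       feature frequency
#> 1     parenchyma SER skewness        60
#> 2           parenchyma PE std        25
#> 3 parenchyma rate in skewness        25

cl <- cluster_bpe(tab, restarts = 50, seed = 1)
cl$composition$tn_in_enriched
#> [1] 11
```

Adding the BPE textures lifts the cross-validated AUC from 0.690 to 0.890
and sensitivity from 15% to 45% at essentially unchanged specificity; the
most frequently selected features are parenchymal (BPE) statistics, and all
11 TN cases fall in one k-means partition of the BPE z-scores alone. Note
the metrics describe this synthetic cohort, not patient data.

The imaging side runs the same way from a phantom:

```r
ph   <- generate_dce_phantom(phantom_spec(class_label = "TN", seed = 3))
br   <- segment_breast(ph$volume)                      # Dice 1.00 vs truth
maps <- parametric_maps(ph$volume, ph$masks$breast)
extract_lesion_features(maps, ph$masks)["parenchyma rate in std"]
#> parenchyma rate in std
#>               10.858
```

A command-line interface wrapping the same functions is installed at
`inst/cli/radbpe` (subcommands `simulate`, `segment`, `kinetics`,
`features`, `classify`, `cluster`, `run`), and `run_pipeline()` executes a
JSON-configured end-to-end run with a seed/digest manifest.

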