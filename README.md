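# ecgblend

Alpha-blended dual-branch time-frequency classification of ECG signals in R.

## The problem

Single-lead ECG recordings from three clinical cohorts — cardiac arrhythmia
(ARR), congestive heart failure (CHF) and normal sinus rhythm (NSR) — can be
told apart from the time-frequency structure of a few seconds of signal. Two
image views of the same segment carry complementary information: the
**scalogram** (continuous wavelet transform magnitude,
`W(a,b) = (1/a) ∫ f(t) ψ*((t−b)/a) dt`, rendered at 227×227 pixels) keeps
detailed spectral intensity, while its **binarized** counterpart (grayscale
thresholded at the mid-gray value 128) keeps only the spatial support of
strong time-frequency activity. `ecgblend` fuses convolutional features from
both views by alpha blending,

```
F = α · F_S + (1 − α) · F_B ,   α ∈ [0, 1]
```

and classifies the fused representation with a class-weighted dense softmax
head or a classical ML head (SVM, random forest, KNN, XGBoost). `α = 1` is a
scalogram-only model, `α = 0` a binary-only model; intermediate α controls
how much each modality contributes. The package ships the full experiment
harness (single-branch ablation, α × split sweeps, ML-head sweeps, 5-fold
stratified cross-validation), feature diagnostics (mean activation maps,
t-SNE embeddings, within-cluster sum of squares), and a parametric
three-class synthetic ECG generator with the 96/30/36 class imbalance of the
public 162-recording PhysioNet bundle, so everything is testable offline.

It is aimed at researchers studying feature-level fusion of time-frequency
representations for biomedical signals, and at anyone who needs a fully
seeded, dependency-light reference implementation of this architecture.

## Worked example

```r
library(ecgblend)

# a synthetic 162-record cohort with the study's 96/30/36 imbalance
grid <- experiment_grid(seed = 42, alphas = c(0, 0.5, 0.7, 1), splits = 0.7)
prep <- prepare_experiment(grid)     # images every record once, caches features

run_ablation(grid, prep)             # single-branch baselines
#> # A tibble: 2 x 4
#>   arch           split accuracy wall_time_s
#>   <chr>          <dbl>    <dbl>       <dbl>
#> 1 scalogram_only   0.7    0.878        53.1
#> 2 binary_only      0.7    0.959        47.6

run_alpha_sweep(grid, prep)          # blended cells; alpha endpoints match above
#> # A tibble: 4 x 4
#>   alpha split accuracy wall_time_s
#>   <dbl> <dbl>    <dbl>       <dbl>
#> 1   0     0.7    0.959        44.0
#> 2   0.5   0.7    0.939        38.6
#> 3   0.7   0.7    0.959        40.2
#> 4   1     0.7    0.878        36.1

cv <- run_cv(grid, k = 5, alpha = 0.7, prep = prep)
sprintf("CV accuracy %.2f%% +/- %.2f%%", 100 * attr(cv, "mean"), 100 * attr(cv, "sd"))
#> [1] "CV accuracy 98.12% +/- 4.19%"
```

The ablation rows are the two single-modality baselines; the sweep's
α = 1 / α = 0 rows reproduce them exactly (shared splits, seeds and branch
weights), and the blended cell at the default proportion α = 0.7 beats the
weaker branch and matches the stronger one — at other seeds it typically
reaches 1.00, above both baselines. Accuracy is `trace/total` of the 3×3
confusion matrix on the held-out 30 %.

Lower-level pieces are exposed individually: `cwt_filter_bank()` /
`cwt_coefficients()` for the wavelet transform, `render_scalogram()`,
`to_grayscale()`, `binarize()` (fixed threshold or Otsu) for imaging,
`build_model()` / `train_model()` / `evaluate()` for the classifier,
`extract_blended_features()` + `fit_head()` for the ML heads, and
`embed_tsne()` / `wcss()` / `mean_activation_map()` for diagnostics. A thin
CLI over these functions lives at `inst/scripts/ecgblend.R`
(verbs `generate`, `imaging`, `ablate`, `sweep`, `mlsweep`, `cv`,
`diagnose`).

## Using real recordings

Recordings enter through a plain-text layout: one single-column CSV per
record plus a `manifest.csv` with header `record_id,path,label`
(`load_manifest()` / `load_records()`). Convert WFDB or MATLAB-bundle data
to that layout with your tool of choice, then point
`experiment_grid(dataset = "directory", dir = ...)` at it; with the real
162-recording bundle the α sweep at 70:30 is expected to peak at or near
α = 0.7 and exceed both ablation baselines.

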