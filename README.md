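# harpipe

Human activity recognition from body-worn inertial sensors, as one tested
R pipeline. Wearable streams (tri-axial accelerometer/gyroscope channels,
one labeled sample per row) arrive with missing, duplicated and corrupted
records; `harpipe` cleans them, turns fixed-length windows into
translation-stable wavelet-scattering features, searches for a compact
discriminative feature subset, and classifies activities (walking,
blinking, standing, sitting, emergency) with a parameter-shared neural
head — reporting accuracy, precision, recall and F-score under a
stratified 80/20 split. A seeded synthetic generator reproduces the whole
study without any downloads.

The pipeline stages and their core constructions:

- **Cleaning (mode-integrated binning).** Per-channel binning with bin-mean
  smoothing; missing values imputed with the grouped-data mode
  `M = l + t (F^m − F^p) / ((F^m − F^p) + (F^m − F^s))` of the modal bin;
  exact consecutive duplicates removed.
- **Discretization (entropy + candidate-k k-means).** Histogram-entropy
  channel weights, 1-D Lloyd k-means over a candidate list of cluster
  counts, k chosen by mean silhouette, values quantized to the nearest
  centroid.
- **Feature extraction (Haar/Symlet wavelet scattering).** Order-2
  scattering `S0 = x∗η`, `S1[j] = |x∗ψ_j|∗η`,
  `S2[j1,j2] = ||x∗ψ_j1|∗ψ_j2|∗η` (j2 > j1) with dyadic Haar band-passes,
  a Symlet-4 derived low-pass, circular convolutions and global average
  pooling: `n_channels · (1 + J + J(J−1)/2)` features per window.
- **Feature selection (binomial-step Golden Eagle search).** Positions in
  `[0,1]^M` decode to masks; attack steps toward memorized prey plus
  cruise steps on the tangent hyperplane, with elementwise
  `Binomial(w1, p)/w1` step factors; wrapper fitness = margin-augmented
  3-fold nearest-centroid CV accuracy minus a small sparsity penalty.
- **Post-processing (scatter matrix).** `S = Σ (x_i − x̄)(x_i − x̄)ᵀ` on the
  training split; features z-scored by `sqrt(diag(S)/n)`.
- **Classification (shared-filter Lego network).** Fragments of the feature
  vector convolved with a small bank of shared filters selected by one-hot
  masks, split-transform-merge layers, softmax head, trained by
  explicit-Euler gradient descent on cross-entropy.

See `vignettes/methods.Rmd` for assumptions, defaults and limitations.

## Worked example

```r
library(harpipe)

cfg <- list(data = list(n_windows_per_class = 50, window_len = 64),
            selection = list(pop_size = 15, iter_max = 50),
            classifier = list(epochs = 120), seed = 42)
res <- run_pipeline(cfg)
print(res$metrics)
#> <metric_report> accuracy 86.000%, macro P 87.039% R 86.000% F 84.714%
res$report$n_selected
#> [1] 5
res$models$selection$selected_names
#> [1] "ch_0.S1.1" "ch_0.S1.2" "ch_0.S1.4" "ch_2.S1.2" "ch_2.S1.4"
```

The report says: on a 5-class synthetic study with 50 windows per class,
the held-out windows are classified with 86% accuracy; the eagle search
kept 5 of 33 scattering features — first-order coefficients whose scales
separate the class frequencies. At the default study size (200 windows
per class, 128-sample windows, seed 1) the pipeline reaches 100% held-out
accuracy, while a permuted-label control stays at chance (~20% for 5
classes).

Each stage is also usable on its own (`clean_records()`,
`fit_discretizer()`, `build_filter_bank()` / `extract_features()`,
`select_features()`, `scatter_summary()`, `train_network()`,
`compute_metrics()`), and `inst/cli/harpipe` wraps simulation and the full
pipeline for shell use:

```sh
Rscript inst/cli/harpipe pipeline --seed 1 --out out/
```

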