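# eegmicronet

Feature extraction and patient-wise classification for short, discharge-free
multichannel EEG, aimed at the differential problem of epilepsy versus
psychogenic non-epileptic seizures (PNES): between events the EEG of the two
groups looks alike, and the question is which quantitative descriptions of a
16-second interictal epoch still separate them. The package implements three
feature families over the canonical frequency sub-bands (delta 1–4, theta
4–8, alpha 9–13, beta 14–30, gamma 30–40 Hz):

* **Per-channel signal features** — energy `E = Σ xᵢ²`, Shannon and Rényi
  (α = 2) amplitude entropies, normalized spectral entropy
  `SE = −Σ Pₙ log Pₙ / log N` over the band, and three fractal dimensions
  (box-counting, Higuchi with `K_max = 20`, Katz).
* **Functional networks from horizontal visibility graphs** — each channel
  becomes an HVG (samples connect iff all intermediate samples lie strictly
  below both), pairwise synchronization is the lag-maximized
  cross-correlation of the standardized HVG degree sequences, and the
  weighted 27×27 network is summarized by Onnela clustering, strength,
  betweenness (edge lengths 1/|w|), eigenvector centrality and λ_max.
* **EEG microstates** — global field power `GFP(t)` (across-channel SD),
  topographies at GFP peaks pooled over subjects, polarity-invariant
  modified K-means (assignment by squared spatial correlation, prototype =
  dominant eigenvector of the cluster scatter), model order selected by the
  CV criterion `CV = σ̂²((C−1)/(C−K−1))²`, back-fitting by global map
  dissimilarity `GMD = ‖x/GFPₓ − y/GFP_y‖/√C`, 30-ms small-segment
  rejection, and per-class occurrence / duration / coverage statistics.

Because the motivating clinical recordings are private, the package ships a
synthetic 27-channel, 256-Hz generator that plants band-limited microstate
structure (semi-Markov topography sequences with exact long-run coverage)
and a controllable beta-band coverage difference between groups, so every
stage — including the patient-paired 5×5 = 25-fold cross-validated
classifier battery (kNN, linear/RBF SVM, decision tree, random forest,
gradient boosting) and the leave-one-band-out / leave-one-feature-out
importance protocols — is verifiable end to end at desk scale.

## Worked example

A small planted experiment — 2 patients per group, 3 beta-band epochs each,
group difference planted in beta microstate coverage:

```r
library(eegmicronet)

cfg <- generator_config(patients_per_group = 2, epochs_per_patient = 3,
                        coverage_shift = 0.2, seed = 7)
spec <- experiment_spec(feature_family = "microstate", bands = "beta",
                        classifiers = c("knn", "random_forest"),
                        config = cfg, seed = 1)
out <- run_experiment(spec)

out$models$beta
#> <microstate_model> K = 3, band = beta, CV = 1.491, GEV = 0.695
print(out$results, digits = 3)
#>      classifier precision recall accuracy specificity   auc
#> 1           knn         1  0.833    0.917           1 0.958
#> 2 random_forest         1  1.000    1.000           1 1.000
```

Reading: the global beta-band model recovered the three planted microstate
classes (`K = 3`) and explains 69.5% of the GFP²-weighted topographic
variance; under the patient-paired split (here 2×2 = 4 folds) both
classifiers separate the groups from the planted coverage shift, kNN
misclassifying one positive epoch (recall 0.833), random forest none. The
feature table (`out$features`) holds one row per 16-s epoch with columns
like `beta_coverage_2`; with `coverage_shift = 0` the same pipeline sits at
chance, which is the package's null calibration.

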