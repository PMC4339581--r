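# simcadx

Texture-based computer-aided classification of healthy versus
osteoarthritic cartilage in 3-D gray-level volumes of interest (VOIs),
for researchers working with high-resolution (e.g. phase-contrast CT)
imaging of cartilage — and, more generally, for anyone who needs
dimension reduction with a *strict* train/test separation inside a
patient-constrained cross-validation protocol.

Healthy cartilage shows columnar chondrocyte alignment in the radial
zone; osteoarthritic cartilage shows disorganized chondrocyte
clustering. The package quantifies that difference and carries it
through a complete, leakage-free supervised pipeline:

1. **Scaling index method (SIM).** Every voxel of a VOI is a 4-D point
   `(x, y, z, s·g)` (spatial coordinates plus scaled gray level) and
   receives a local scaling index

   &alpha;<sub>i</sub> = 2 &Sigma;<sub>j</sub> (d<sub>ij</sub>/r)²
   e<sup>−(d<sub>ij</sub>/r)²</sup> / &Sigma;<sub>j</sub>
   e<sup>−(d<sub>ij</sub>/r)²</sup>,

   where `d_ij` is the 4-D Euclidean distance and `r` the neighborhood
   radius (default 1 voxel). The nine deciles of the per-VOI
   &alpha;-distribution form a 9-D geometric feature vector.
2. **Feature reduction on training data only**: PCA, Sammon mapping,
   t-SNE or the exploratory observation machine (XOM) in 2, 3 or 5
   dimensions — or univariate feature selection by mutual information
   with adaptively binned histograms.
3. **Out-of-sample extension**: test vectors enter a fitted embedding as
   convex combinations F(X) = &Sigma; a<sub>i</sub>(X) Y<sub>i</sub>
   with Shepard inverse-distance weights or normalized Gaussian RBF
   weights (PCA projects directly).
4. **Patient-constrained classification**: per iteration, 200 rows per
   patient are subsampled, one healthy and one osteoarthritic patient
   are held out for testing, hyperparameters are tuned on a stratified
   70/30 inner split, and a linear-kernel support vector regression
   scores the held-out patients by ROC/AUC. Fifty iterations give an
   AUC distribution per configuration.
5. **Statistics**: Wilcoxon signed-rank comparisons of AUC distributions
   with Holm–Bonferroni correction, and Dunn's separation index for
   embedding views.

Synthetic generators (`generate_voi()`, `generate_feature_dataset()`)
produce volumes and feature sets with the structure the analysis
assumes, so the whole pipeline is testable without imaging data. A
minimal MAT v5 reader (`load_s1_dataset()`) ingests deposited feature
datasets from MATLAB-compatible containers.

## Worked example

```r
library(simcadx)

## volumes -> SIM features
vois <- c(
  lapply(1:4, function(s) generate_voi("healthy", side = 15, n_inclusions = 6,
                                       noise_sd = 0.5, seed = s,
                                       patient_id = paste0("H", (s + 1) %/% 2))),
  lapply(1:4, function(s) generate_voi("osteoarthritic", side = 15,
                                       n_inclusions = 6, noise_sd = 0.5,
                                       seed = 100 + s,
                                       patient_id = paste0("O", (s + 1) %/% 2)))
)
features <- extract_features(vois, radius_r = 1)
features
#> Labeled feature set: 8 rows x 9 features
#>   healthy: 4, osteoarthritic: 4
#>   patients: 4
round(features$features[c(1, 5), ], 3)
#>        q10   q20   q30   q40   q50   q60   q70   q80   q90
#> [1,] 0.596 1.323 2.174 2.515 2.689 2.800 2.933 3.042 3.146
#> [2,] 0.703 1.171 1.773 2.307 2.548 2.677 2.788 2.920 3.069
```

Each row is the decile summary of one VOI's &alpha;-distribution: low
deciles reflect locally flat or point-like structure, high deciles
space-filling structure; the healthy (row 1) and diseased (row 2)
profiles differ in how quickly the distribution rises.

```r
## feature-level protocol: 5 patients, moderate class overlap
data <- generate_feature_dataset(n_patients = 5, n_per_patient = 300,
                                 dim = 9, class_separation = 2, seed = 42)
cfg <- experiment_config("pca", target_dim = 2, n_iterations = 10,
                         master_seed = 7)
res <- run_experiment(data, cfg)
res
#> AUC over 10 iterations: 0.927 +/- 0.009  [pca, dim 2, oos pca_direct]
round(res$aucs, 3)
#>  [1] 0.924 0.941 0.913 0.920 0.941 0.930 0.924 0.931 0.929 0.917
```

A 2-D PCA representation of the 9-D features classifies held-out
patients at mean AUC 0.93 — essentially the Bayes limit for this
separation (&Phi;(2/&radic;2) &approx; 0.92), so nothing was lost in the
reduction. `compare_auc_distributions()` then tests such configurations
against each other.

A command-line front end is installed at `exec/simcadx` with
subcommands `sim-extract`, `embed`, `extend`, `mi-rank`, `experiment`
and `compare`; run it without arguments for usage.

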