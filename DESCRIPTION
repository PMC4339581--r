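Package: simcadx
Title: Scaling-Index Texture Features and Patient-Constrained
    Classification of Cartilage Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computer-aided classification of healthy versus osteoarthritic
    cartilage texture in 3-D gray-level volumes of interest. Implements the
    scaling index method (SIM) transform with Gaussian shaping functions and
    its 9-quantile geometric feature summary; linear and non-linear dimension
    reduction (PCA, Sammon mapping, t-SNE, the exploratory observation
    machine) fitted on training data only, with out-of-sample extension of
    test points by Shepard inverse-distance interpolation or normalized
    Gaussian radial basis function approximation; mutual-information feature
    selection with adaptive histogram binning; support vector regression
    under patient-constrained repeated cross-validation with ROC/AUC scoring;
    and statistical comparison of AUC distributions (Wilcoxon signed-rank,
    Holm-Bonferroni) plus Dunn's cluster separation index. Includes a
    synthetic generator for volumes and feature sets and a reader for MAT v5
    feature containers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
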