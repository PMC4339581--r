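#' Adaptive histogram bin count
#'
#' Number of histogram bins used when discretizing a feature for mutual
#' information estimation, grown with both sample size and tail weight:
#' \deqn{n_f = \lceil \log_2 N + 1 + \log_2(1 + \kappa N / 6) \rceil}
#' with \eqn{\kappa} the estimated excess kurtosis of the sample (moment
#' estimator; Gaussian data give 0), clipped below at zero so the logarithm
#' argument stays at least 1. `bin_rule = "doane"` replaces the last term's
#' \eqn{\kappa N / 6} by the Doane-style \eqn{\kappa \sqrt{N / 6}}; the rule
#' used is recorded on the result.
#'
#' @param values numeric vector, length >= 4 (kurtosis must be estimable).
#' @param bin_rule `"literal"` (default) or `"doane"`.
#' @return Integer bin count (>= 1) with attributes `kurtosis_used` and
#'   `bin_rule`.
#' @export
adaptive_bin_count <- function(values, bin_rule = c("literal", "doane")) {
  bin_rule <- match.arg(bin_rule)
  values <- as.numeric(values)
  N <- length(values)
  if (N < 4L) stop("need at least 4 values to estimate kurtosis")
  if (anyNA(values) || !all(is.finite(values))) stop("values must be finite")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  kappa <- if (m2 > 0) mean((values - m)^4) / m2^2 - 3 else 0
  kappa <- max(kappa, 0)
  tail_term <- switch(bin_rule,
                      literal = kappa * N / 6,
                      doane = kappa * sqrt(N / 6))
  nf <- ceiling(log2(N) + 1 + log2(1 + tail_term))
  structure(max(1L, as.integer(nf)), kurtosis_used = kappa,
            bin_rule = bin_rule)
}

#' Mutual information between a feature and class labels
#'
#' Discretizes the feature into `n_bins` equal-width bins over its min-max
#' range (values on the right edge fall in the last bin), forms the joint
#' probability table with the two class labels by counting, and computes
#' \deqn{I(f, y) = \sum_{y} \sum_{f} P(f, y)
#'   \log_2 \frac{P(f, y)}{P(f) P(y)}}
#' in bits, with the convention \eqn{0 \log 0 = 0}. The marginal and joint
#' entropies computed from the same histogram are returned so the identity
#' \eqn{I = H(f) + H(y) - H(f, y)} can be verified on every score.
#'
#' Note equal-width binning makes the score sensitive to non-linear (though
#' not to affine) monotone transforms of the feature; the binning convention
#' is recorded on the result.
#'
#' @param feature numeric vector.
#' @param labels class labels (two classes, both present).
#' @param n_bins histogram bin count; default from [adaptive_bin_count()].
#' @param bin_rule passed to [adaptive_bin_count()].
#' @return An object of class `mi_score`: list with `mi_bits`, `n_bins`,
#'   `kurtosis_used`, entropies `h_feature`, `h_labels`, `h_joint` (bits),
#'   and `binning = "equal_width"`.
#' @export
mutual_information <- function(feature, labels, n_bins = NULL,
                               bin_rule = c("literal", "doane")) {
  bin_rule <- match.arg(bin_rule)
  feature <- as.numeric(feature)
  labels <- as.factor(labels)
  if (length(feature) != length(labels)) stop("length mismatch")
  if (nlevels(droplevels(labels)) != 2L) {
    stop("labels must contain exactly 2 classes (both present)")
  }
  labels <- droplevels(labels)
  kappa <- NA_real_
  if (is.null(n_bins)) {
    n_bins <- adaptive_bin_count(feature, bin_rule)
    kappa <- attr(n_bins, "kurtosis_used")
    n_bins <- as.integer(n_bins)
  }
  N <- length(feature)
  rng <- range(feature)
  bins <- if (diff(rng) == 0) rep(1L, N) else {
    b <- floor((feature - rng[1]) / diff(rng) * n_bins) + 1L
    pmin(b, n_bins)  # right-edge values belong to the last bin
  }
  joint <- table(factor(bins, levels = seq_len(n_bins)), labels) / N
  pf <- rowSums(joint)
  py <- colSums(joint)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  # Eq-style double sum with 0 log 0 = 0
  terms <- joint * (log2(ifelse(joint > 0, joint, 1)) -
                      log2(outer(ifelse(pf > 0, pf, 1),
                                 ifelse(py > 0, py, 1))))
  structure(
    list(mi_bits = sum(terms),
         n_bins = n_bins,
         kurtosis_used = kappa,
         h_feature = -sum(plogp(pf)),
         h_labels = -sum(plogp(py)),
         h_joint = -sum(plogp(joint)),
         binning = "equal_width"),
    class = "mi_score"
  )
}

#' @export
print.mi_score <- function(x, ...) {
  cat(sprintf("MI = %.4f bits (%d equal-width bins)\n", x$mi_bits, x$n_bins))
  invisible(x)
}

#' Select the top features by mutual information with the class labels
#'
#' Ranks every feature column of the training data by its mutual
#' information with the class labels and returns the indices of the `k`
#' highest-scoring features. Ties break deterministically toward the lower
#' column index. Ranking must be computed on training rows only; test rows
#' never enter.
#'
#' @param train a [labeled_feature_set()] of training rows.
#' @param k number of features to keep, `1 <= k <= D`.
#' @param bin_rule passed to [mutual_information()].
#' @return Integer vector of `k` column indices in decreasing MI order,
#'   with the full score table attached as `attr(, "scores")`.
#' @export
select_top_features <- function(train, k, bin_rule = c("literal", "doane")) {
  stopifnot(inherits(train, "labeled_feature_set"))
  bin_rule <- match.arg(bin_rule)
  D <- ncol(train$features)
  if (k < 1L || k > D) stop("'k' must satisfy 1 <= k <= D")
  scores <- lapply(seq_len(D), function(j) {
    mutual_information(train$features[, j], train$labels, bin_rule = bin_rule)
  })
  mi <- vapply(scores, `[[`, 0, "mi_bits")
  ord <- order(-mi, seq_len(D))
  structure(ord[seq_len(k)],
            scores = data.frame(
              feature_index = seq_len(D),
              mi_bits = mi,
              n_bins = vapply(scores, `[[`, 0L, "n_bins"),
              kurtosis_used = vapply(scores, `[[`, 0, "kurtosis_used")))
}
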