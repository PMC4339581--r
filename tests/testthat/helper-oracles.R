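# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (R dist()/double loops instead of the compiled
# kernels) so agreement is informative.

# All-pairs scaling index evaluation of a 3-D volume via the 4-D point
# cloud and stats::dist.
brute_alpha <- function(vol, r = 1, iscale = 1) {
  dims <- dim(vol)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  pts <- cbind(idx, iscale * as.vector(vol))
  U2 <- as.matrix(dist(pts))^2 / r^2
  W <- exp(-U2)
  array(2 * rowSums(U2 * W) / rowSums(W), dims)
}

# AUC by explicit concordant/tied pair counting.
brute_auc <- function(scores, labels, positive = "osteoarthritic") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sn))
}

# Mutual information of a discrete joint count table, in bits.
table_mi <- function(counts) {
  p <- counts / sum(counts)
  pf <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pf[i] * py[j]))
  }
  s
}

# Sammon stress from scratch (pairs with positive input distance).
stress_oracle <- function(X, Y) {
  D <- as.matrix(dist(X)); d <- as.matrix(dist(Y))
  keep <- upper.tri(D) & D > 0
  sum((D[keep] - d[keep])^2 / D[keep]) / sum(D[keep])
}

random_lfs <- function(n = 40, dim = 4, seed = 1, separation = 0,
                       n_patients = 4) {
  generate_feature_dataset(n_patients, ceiling(n / n_patients), dim,
                           separation, seed = seed)
}

python_bin <- function() Sys.which("python")
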