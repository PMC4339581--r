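#' Wilcoxon signed-rank test for paired AUC distributions
#'
#' Two-sided paired test on the differences `a - b`. Zero differences are
#' dropped before ranking (the classic convention; the effective sample
#' size is reported). For `n <= 25` retained pairs the exact two-sided
#' p-value is computed from the full distribution of the positive-rank sum
#' over all sign assignments (handled by convolution over the midranks, so
#' ties are exact too); above that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b paired numeric vectors of equal length (e.g. per-iteration
#'   AUCs of two configurations).
#' @return List with `statistic` (positive-rank sum `W`), `p_value`,
#'   `n_used` (pairs after zero removal) and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate input: all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of 2W by convolution over doubled midranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[w + 1] = #assignments with doubled sum w
    f[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), f[seq_len(length(f) - rr)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1L)])
    p_hi <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, n_used = n, method = method)
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Orders the p-values ascending and rejects \eqn{p_{(i)}} while
#' \eqn{p_{(i)} \le \alpha / (m - i + 1)}, stopping at the first failure,
#' which controls the family-wise error rate at \eqn{\alpha}.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level in (0, 1) (default 0.05).
#' @return Logical rejection flags in the original order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1) || anyNA(p)) stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

#' Compare AUC distributions across configurations
#'
#' Pairwise Wilcoxon signed-rank tests over a list of named AUC
#' distributions (paired by iteration), with Holm-Bonferroni correction
#' across the supplied contrast family.
#'
#' @param distributions named list of [run_experiment()] results (or plain
#'   numeric AUC vectors of equal length).
#' @param contrasts two-column character matrix (or list of pairs) naming
#'   the comparisons; default: all pairs.
#' @param alpha family-wise error level.
#' @return Data frame with one row per contrast: the pair, `statistic`,
#'   `p_value` and the Holm-adjusted `rejected` flag.
#' @export
compare_auc_distributions <- function(distributions, contrasts = NULL,
                                      alpha = 0.05) {
  vecs <- lapply(distributions, function(d) {
    if (inherits(d, "auc_distribution")) d$aucs else as.numeric(d)
  })
  if (is.null(names(vecs)) || any(!nzchar(names(vecs)))) {
    stop("'distributions' must be a named list")
  }
  if (is.null(contrasts)) {
    contrasts <- t(utils::combn(names(vecs), 2L))
  } else if (is.list(contrasts)) {
    contrasts <- do.call(rbind, contrasts)
  }
  res <- apply(contrasts, 1L, function(pair) {
    wilcoxon_signed_rank(vecs[[pair[1L]]], vecs[[pair[2L]]])
  })
  out <- data.frame(
    a = contrasts[, 1L], b = contrasts[, 2L],
    statistic = vapply(res, `[[`, 0, "statistic"),
    p_value = vapply(res, `[[`, 0, "p_value")
  )
  out$rejected <- holm_bonferroni(out$p_value, alpha)
  out
}

#' Dunn's cluster separation index
#'
#' Minimum inter-cluster point-pair distance divided by the maximum
#' intra-cluster diameter (all Euclidean). Larger values indicate
#' better-separated, more compact clusters.
#'
#' @param points numeric matrix of coordinates (rows = points).
#' @param labels cluster labels (>= 2 clusters, each non-empty).
#' @return The separation index (numeric scalar).
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  if (nrow(points) != length(labels)) stop("length mismatch")
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 clusters")
  D <- as.matrix(dist(points))
  same <- outer(labels, labels, `==`)
  diag_mask <- diag(TRUE, nrow(D))
  intra <- D[same & !diag_mask]
  max_diam <- if (length(intra)) max(intra) else 0
  if (max_diam == 0) {
    stop("zero intra-cluster diameter everywhere: Dunn index undefined ",
         "(division by zero)")
  }
  min(D[!same]) / max_diam
}
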