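#' Out-of-sample mapper
#'
#' Packages a fitted embedding (paired training inputs `X_train` and
#' low-dimension coordinates `Y_train`) with an extension scheme that maps
#' new points into the embedding as a convex combination
#' \deqn{F(X) = \sum_i a_i(X) Y_i,}
#' with non-negative weights summing to one. Two weighting schemes are
#' available, plus direct projection for PCA models:
#' \describe{
#'   \item{shepard}{inverse-distance weights
#'     \eqn{a_i \propto d(X, X_i)^{-p}}; an exact (or near-exact, within
#'     1e-12) hit on a training point returns that point's coordinates, the
#'     limit value of the weights.}
#'   \item{grbf}{normalized Gaussian radial-basis weights
#'     \eqn{a_i \propto e^{-\|X - X_i\|^2 / 2\rho^2}}, evaluated with a
#'     max-shifted exponent for numerical stability.}
#'   \item{pca_direct}{the linear map \eqn{(X - \mu) C^\top} of a fitted
#'     [pca_fit()] model.}
#' }
#'
#' @param X_train,Y_train row-matched training inputs and embedding
#'   coordinates; taken from `embedding` if supplied.
#' @param scheme `"shepard"`, `"grbf"` or `"pca_direct"`.
#' @param power_p Shepard inverse-distance power (> 0; default 2).
#' @param rho GRBF kernel width (> 0; default: median pairwise training
#'   distance).
#' @param embedding an [embedding_result] or [pca_fit()] model supplying
#'   `X_train`/`Y_train` (and the PCA model for `pca_direct`).
#' @return An object of class `oos_mapper`.
#' @export
oos_mapper <- function(embedding = NULL,
                       scheme = c("shepard", "grbf", "pca_direct"),
                       X_train = NULL, Y_train = NULL,
                       power_p = 2, rho = NULL) {
  scheme <- match.arg(scheme)
  pca_model <- NULL
  if (!is.null(embedding)) {
    if (inherits(embedding, "pca_model")) {
      pca_model <- embedding
      X_train <- X_train %||% (embedding$Y_train * NA)  # unused for pca_direct
      Y_train <- Y_train %||% embedding$Y_train
    } else if (inherits(embedding, "embedding_result")) {
      X_train <- X_train %||% embedding$X_train
      Y_train <- Y_train %||% embedding$Y_train
    } else stop("'embedding' must be an embedding_result or pca_model")
  }
  if (scheme == "pca_direct") {
    if (is.null(pca_model)) stop("'pca_direct' requires a fitted pca_model")
  } else {
    if (is.null(X_train) || is.null(Y_train)) {
      stop("'X_train' and 'Y_train' are required")
    }
    X_train <- as.matrix(X_train); Y_train <- as.matrix(Y_train)
    if (nrow(X_train) == 0L) stop("empty training set")
    if (nrow(X_train) != nrow(Y_train)) stop("X_train/Y_train row mismatch")
  }
  if (scheme == "shepard" && (!is.finite(power_p) || power_p <= 0)) {
    stop("'power_p' must be > 0")
  }
  if (scheme == "grbf") {
    rho <- rho %||% stats::median(dist(X_train))
    if (!is.finite(rho) || rho <= 0) stop("'rho' must be > 0")
  }
  structure(
    list(X_train = X_train, Y_train = Y_train, scheme = scheme,
         power_p = power_p, rho = rho, pca_model = pca_model),
    class = "oos_mapper"
  )
}

# squared Euclidean cross-distances, n_test x n_train
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Extend out-of-sample points into an embedding
#'
#' Dispatches on the mapper's scheme; see [oos_mapper()] for the weight
#' definitions and [shepard_extend()], [grbf_extend()], [pca_project()] for
#' the individual schemes.
#'
#' @param mapper an [oos_mapper()].
#' @param X_test matrix of out-of-sample feature vectors (rows).
#' @return Matrix of low-dimension coordinates, one row per test point.
#' @export
oos_extend <- function(mapper, X_test) {
  stopifnot(inherits(mapper, "oos_mapper"))
  switch(mapper$scheme,
         shepard = shepard_extend(mapper, X_test),
         grbf = grbf_extend(mapper, X_test),
         pca_direct = pca_project(mapper, X_test))
}

#' @rdname oos_extend
#' @details `shepard_extend` uses inverse-distance-power weights; test
#'   points within 1e-12 of a training point receive the (well-defined)
#'   limit value, i.e. the average of the coinciding training coordinates.
#' @export
shepard_extend <- function(mapper, X_test) {
  stopifnot(inherits(mapper, "oos_mapper"), mapper$scheme == "shepard")
  X_test <- matrix_rows(X_test, ncol(mapper$X_train))
  d <- sqrt(cross_dist2(X_test, mapper$X_train))
  p <- mapper$power_p
  out <- matrix(0, nrow(X_test), ncol(mapper$Y_train))
  for (i in seq_len(nrow(X_test))) {
    hits <- which(d[i, ] < 1e-12)
    if (length(hits)) {
      out[i, ] <- colMeans(mapper$Y_train[hits, , drop = FALSE])
    } else {
      w <- d[i, ]^(-p)
      w <- w / sum(w)
      out[i, ] <- w %*% mapper$Y_train
    }
  }
  out
}

#' @rdname oos_extend
#' @details `grbf_extend` uses normalized Gaussian weights with kernel
#'   width `rho`; exponents are shifted by their per-point maximum before
#'   exponentiation so that large distances cannot underflow all weights.
#' @export
grbf_extend <- function(mapper, X_test) {
  stopifnot(inherits(mapper, "oos_mapper"), mapper$scheme == "grbf")
  X_test <- matrix_rows(X_test, ncol(mapper$X_train))
  e <- -cross_dist2(X_test, mapper$X_train) / (2 * mapper$rho^2)
  e <- e - apply(e, 1, max)
  w <- exp(e)
  w <- w / rowSums(w)
  w %*% mapper$Y_train
}

#' @rdname oos_extend
#' @param model used by `pca_project`: an [oos_mapper()] with scheme
#'   `pca_direct`, or a [pca_fit()] model directly.
#' @export
pca_project <- function(model, X_test) {
  pm <- if (inherits(model, "oos_mapper")) {
    stopifnot(model$scheme == "pca_direct")
    model$pca_model
  } else if (inherits(model, "pca_model")) model
  else stop("'model' must be an oos_mapper or pca_model")
  X_test <- matrix_rows(X_test, length(pm$mean))
  sweep(X_test, 2, pm$mean) %*% t(pm$components)
}

matrix_rows <- function(X, D) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != D) stop("test points have dimension ", ncol(X),
                         " but the mapper expects ", D)
  X
}
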