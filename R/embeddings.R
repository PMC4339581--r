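#' @title Embedding result container
#' @description Internal constructor pairing training inputs with their
#'   low-dimension coordinates; the basis of out-of-sample extension.
#' @keywords internal
embedding_result <- function(method, X_train, Y_train, params,
                             final_cost = NA_real_) {
  stopifnot(nrow(X_train) == nrow(Y_train))
  structure(
    list(method = method, X_train = X_train, Y_train = Y_train,
         params = params, final_cost = final_cost),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("%s embedding: %d points, %d-D -> %d-D",
              x$method, nrow(x$X_train), ncol(x$X_train), ncol(x$Y_train)))
  if (is.finite(x$final_cost)) cat(sprintf(", final cost %.6g", x$final_cost))
  cat("\n")
  invisible(x)
}

#' Principal component analysis
#'
#' Mean-centered orthogonal linear projection maximizing retained variance.
#' Unlike the non-linear embeddings, a PCA model maps new points directly
#' (see [pca_project()]), so no interpolation-based extension is needed.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param d number of components, `1 <= d <= min(N - 1, D)`.
#' @return An object of class `pca_model`: list with `mean` (column means),
#'   `components` (`d x D`, orthonormal rows), `explained_variance`
#'   (non-increasing) and `Y_train` (`N x d` training scores).
#' @export
pca_fit <- function(X, d) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (d < 1L || d > min(n - 1L, D)) {
    stop("'d' must satisfy 1 <= d <= min(N - 1, D)")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  structure(
    list(mean = pc$center,
         components = t(pc$rotation[, seq_len(d), drop = FALSE]),
         explained_variance = pc$sdev[seq_len(d)]^2,
         Y_train = pc$x[, seq_len(d), drop = FALSE]),
    class = "pca_model"
  )
}

# Sammon stress of a candidate configuration: sum over pairs with D_ij > 0 of
# (D_ij - d_ij)^2 / D_ij, normalized by sum D_ij.
sammon_stress <- function(D, Y) {
  D <- as.matrix(D)
  dy <- as.matrix(dist(Y))
  keep <- upper.tri(D) & D > 0
  sum((D[keep] - dy[keep])^2 / D[keep]) / sum(D[keep])
}

#' Sammon mapping
#'
#' Non-linear embedding minimizing the distance-preservation stress
#' \deqn{E = \frac{1}{\sum_{i<j} D_{ij}} \sum_{i<j}
#'       \frac{(D_{ij} - d_{ij})^2}{D_{ij}},}
#' where \eqn{D_{ij}} are input-space and \eqn{d_{ij}} output-space
#' Euclidean distances. Minimization uses the classic diagonal-Newton
#' descent with step halving (via [MASS::sammon()]); initialization is the
#' PCA projection (deterministic) or a seeded random configuration.
#'
#' Duplicate input rows (pairs at distance zero) would make stress terms
#' singular; they are collapsed before fitting — duplicates share the
#' coordinates of their representative — and a warning is issued.
#'
#' @param X numeric feature matrix.
#' @param d embedding dimension.
#' @param iterations maximum descent iterations.
#' @param seed seed for `init = "random"` (ignored for PCA init).
#' @param init `"pca"` (default) or `"random"`.
#' @param tol stop when the stress improvement falls below `tol`.
#' @return An [embedding_result] with `final_cost` equal to the Sammon
#'   stress of the returned configuration.
#' @export
sammon_fit <- function(X, d, iterations = 200L, seed = NULL,
                       init = c("pca", "random"), tol = 1e-9) {
  X <- as.matrix(X)
  init <- match.arg(init)
  if (nrow(X) < 2L) stop("need at least 2 points")
  dup <- duplicated(X)
  if (any(dup)) {
    warning("dropping ", sum(dup),
            " duplicate input row(s) from the stress sum; duplicates are ",
            "assigned the coordinates of their first occurrence")
  }
  Xu <- X[!dup, , drop = FALSE]
  # map every row to its representative among the unique rows
  key <- apply(X, 1, paste, collapse = "\r")
  map <- match(key, key[!dup])
  if (nrow(Xu) < 2L) stop("fewer than 2 distinct points")

  Dd <- dist(Xu)
  Y0 <- if (init == "pca") {
    sc <- prcomp(Xu, center = TRUE, scale. = FALSE)$x
    k <- min(ncol(sc), d)
    cbind(sc[, seq_len(k), drop = FALSE],
          matrix(0, nrow(Xu), d - k))
  } else {
    with_seed(seed, matrix(rnorm(nrow(Xu) * d), ncol = d))
  }
  # descent requires a duplicate-free initial configuration
  if (any(dist(Y0) == 0)) {
    Y0 <- Y0 + with_seed(seed %||% 0L,
                         matrix(runif(length(Y0), -1e-8, 1e-8), ncol = d))
  }
  fit <- MASS::sammon(Dd, y = Y0, k = d, niter = iterations, trace = FALSE,
                      tol = tol)
  Yu <- fit$points
  embedding_result(
    "sammon", X, Yu[map, , drop = FALSE],
    params = list(iterations = iterations, init = init, seed = seed,
                  tol = tol, n_duplicates = sum(dup),
                  initial_cost = sammon_stress(Dd, Y0)),
    final_cost = sammon_stress(Dd, Yu)
  )
}

# Per-point Gaussian bandwidths matched to a target perplexity by bisection
# on the precision beta = 1 / (2 sigma^2).
tsne_input_probs <- function(D2, perplexity, tol = 1e-5, max_iter = 64L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < tol) break
      if (H > logU) { beta_lo <- beta; beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P
}

#' t-distributed stochastic neighbor embedding
#'
#' Converts pairwise input distances into neighbor probabilities under
#' per-point Gaussian kernels calibrated to a target perplexity, models
#' output similarities with a Student-t (one degree of freedom) kernel, and
#' minimizes the Kullback-Leibler divergence between the two by gradient
#' descent with momentum, adaptive gains and early exaggeration — the
#' reference algorithm's standard optimization schedule.
#'
#' @param X numeric feature matrix (`N >= 4` rows).
#' @param d embedding dimension.
#' @param perplexity effective neighbor count, `1 <= perplexity < N`.
#' @param seed seed for the random initial configuration.
#' @param iterations gradient descent iterations (default 1000).
#' @param eta learning rate.
#' @param exaggeration early exaggeration factor, applied for the first
#'   quarter of the iterations (at most 100).
#' @return An [embedding_result]; `final_cost` is the KL divergence of the
#'   returned configuration, and `params$initial_cost` the KL divergence of
#'   the initial one.
#' @export
tsne_fit <- function(X, d = 2L, perplexity = 30, seed = NULL,
                     iterations = 1000L, eta = 200, exaggeration = 4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 points")
  if (perplexity < 1 || perplexity >= n) {
    stop("'perplexity' must satisfy 1 <= perplexity < N")
  }
  D2 <- as.matrix(dist(X))^2
  P <- tsne_input_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  kl_cost <- function(P, Y) {
    num <- 1 / (1 + as.matrix(dist(Y))^2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    sum(P * log(P / Q)) - sum(diag(P * log(P / Q)))
  }

  with_seed(seed, {
    Y <- matrix(rnorm(n * d, sd = 1e-4), ncol = d)
    initial_cost <- kl_cost(P, Y)
    V <- matrix(0, n, d)
    gains <- matrix(1, n, d)
    stop_exag <- min(100L, max(1L, iterations %/% 4L))
    Pe <- P * exaggeration
    for (it in seq_len(iterations)) {
      Puse <- if (it <= stop_exag) Pe else P
      num <- 1 / (1 + as.matrix(dist(Y))^2); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Puse - Q) * num
      G <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it <= 250L) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8))
      V <- mom * V - eta * gains * G
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    embedding_result(
      "tsne", X, Y,
      params = list(perplexity = perplexity, iterations = iterations,
                    eta = eta, exaggeration = exaggeration, seed = seed,
                    initial_cost = initial_cost),
      final_cost = kl_cost(P, Y)
    )
  })
}

#' Exploratory observation machine (XOM)
#'
#' Topology-preserving embedding by sequential adaptation. A structure
#' hypothesis — uniform random sampling vectors over a low-dimensional
#' domain — drives the placement: at every step a sampling vector `S` is
#' drawn, the best-match input `X'` is the one whose current output lies
#' closest to `S`, and every output moves toward `S` in proportion to a
#' Gaussian cooperativity between its input vector and `X'`:
#' \deqn{Y_i \leftarrow Y_i + \epsilon(t)\,
#'   e^{-\|X_i - X'\|^2 / 2\sigma(t)^2}\,(S - Y_i).}
#' The learning rate \eqn{\epsilon(t)} and neighborhood width
#' \eqn{\sigma(t)} follow exponential-decay annealing between their start
#' and end values.
#'
#' Defaults: sampling domain \eqn{[0, 1]^d}, `100 * N` iterations,
#' \eqn{\sigma} from 20% to 1% of the input-space data diameter, and
#' \eqn{\epsilon} from 0.9 to 0.05. The neighborhood width is the free
#' parameter the classification protocol tunes.
#'
#' @param X numeric feature matrix.
#' @param d embedding dimension.
#' @param sigma_start,sigma_end neighborhood width schedule (input-space
#'   units); defaults are fractions of the data diameter.
#' @param epsilon_start,epsilon_end learning rate schedule (both may be 0,
#'   in which case the initialization is returned unchanged).
#' @param iterations number of adaptation steps (default `100 * N`).
#' @param seed integer seed (initial placement and sampling vectors).
#' @param sampling_domain length-2 bounds of the uniform structure
#'   hypothesis, replicated across the `d` output coordinates.
#' @return An [embedding_result] (`final_cost` is `NA`; XOM's implicit cost
#'   is not evaluated).
#' @export
xom_fit <- function(X, d = 2L, sigma_start = NULL, sigma_end = NULL,
                    epsilon_start = 0.9, epsilon_end = 0.05,
                    iterations = NULL, seed = NULL,
                    sampling_domain = c(0, 1)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stop("empty input")
  if (length(sampling_domain) != 2L || diff(sampling_domain) <= 0) {
    stop("'sampling_domain' must be increasing bounds")
  }
  diam <- if (n > 1L) max(dist(X)) else 1
  if (diam == 0) diam <- 1
  sigma_start <- sigma_start %||% (0.2 * diam)
  sigma_end <- sigma_end %||% (0.01 * diam)
  iterations <- as.integer(iterations %||% (100L * n))
  if (iterations < 1L) stop("'iterations' must be >= 1")
  if (sigma_start <= 0 || sigma_end <= 0 || sigma_end > sigma_start) {
    stop("sigma schedule must be positive and decaying")
  }
  if (epsilon_start < 0 || epsilon_end < 0 || epsilon_end > epsilon_start) {
    stop("epsilon schedule must be non-negative and decaying")
  }
  D2x <- as.matrix(dist(X))^2
  decay <- function(a, b, t) {
    if (iterations == 1L) return(a)
    if (a == 0) return(rep(0, length(t)))
    a * (b / a)^((t - 1) / (iterations - 1))
  }
  tt <- seq_len(iterations)
  with_seed(seed, {
    Y0 <- matrix(runif(n * d, sampling_domain[1], sampling_domain[2]), ncol = d)
    S <- matrix(runif(iterations * d, sampling_domain[1], sampling_domain[2]),
                ncol = d)
    Y <- .xom_adapt_cpp(Y0, S, D2x, decay(sigma_start, sigma_end, tt),
                        decay(epsilon_start, epsilon_end, tt))
    embedding_result(
      "xom", X, Y,
      params = list(sigma_start = sigma_start, sigma_end = sigma_end,
                    epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                    iterations = iterations, seed = seed,
                    sampling_domain = sampling_domain, Y_init = Y0)
    )
  })
}
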