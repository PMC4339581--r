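test_that("PCA recovers an exact low-dimensional subspace", {
  set.seed(4)
  scores <- matrix(rnorm(40 * 2), 40, 2)
  W <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))   # orthonormal 5x2 basis
  X <- scores %*% t(W) + rep(1, 40) %o% rnorm(5)
  m <- pca_fit(X, 2)
  recon <- m$Y_train %*% m$components + rep(1, 40) %o% m$mean
  expect_equal(recon, X, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA directions match an independent eigendecomposition", {
  set.seed(5)
  X <- matrix(rnorm(200), 100, 2) %*% matrix(c(2, 1.2, 0, 0.5), 2, 2)
  m <- pca_fit(X, 1)
  ev <- eigen(cov(X))$vectors[, 1]
  cosang <- abs(sum(m$components[1, ] * ev))
  expect_equal(cosang, 1, tolerance = 1e-8)
  # variance bookkeeping and orthonormal loadings
  m2 <- pca_fit(X, 2)
  expect_lte(sum(m2$explained_variance), sum(diag(cov(X))) + 1e-10)
  expect_true(all(diff(m2$explained_variance) <= 1e-12))
  expect_equal(m2$components %*% t(m2$components), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit(X, 3), "d")
})

test_that("PCA training scores equal the direct projection of the training data", {
  set.seed(6)
  X <- matrix(rnorm(90), 30, 3)
  m <- pca_fit(X, 2)
  expect_equal(pca_project(m, X), m$Y_train, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Sammon mapping achieves zero stress on embeddable configurations", {
  X2 <- matrix(c(0, 0, 0, 3), 2, 2, byrow = TRUE)
  e2 <- sammon_fit(X2, 1)
  expect_lt(e2$final_cost, 1e-10)
  expect_equal(abs(diff(e2$Y_train[, 1])), 3, tolerance = 1e-5)

  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  es <- sammon_fit(square, 2)
  expect_lt(es$final_cost, 1e-6)
})

test_that("Sammon stress on three equidistant points matches a dense grid search", {
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))  # equilateral, side 1
  e <- sammon_fit(X, 1, iterations = 500)
  # oracle: 1-D configs (0, a, b) on a dense grid
  ab <- expand.grid(a = seq(-2, 2, by = 0.005), b = seq(-2, 2, by = 0.005))
  D <- as.matrix(dist(X))
  sumD <- D[1, 2] + D[1, 3] + D[2, 3]
  st <- ((D[1, 2] - abs(ab$a))^2 / D[1, 2] +
         (D[1, 3] - abs(ab$b))^2 / D[1, 3] +
         (D[2, 3] - abs(ab$b - ab$a))^2 / D[2, 3]) / sumD
  expect_equal(e$final_cost, min(st), tolerance = 1e-3)
})

test_that("Sammon stress is invariant under rigid motions of the output", {
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  Y <- matrix(rnorm(40), 20, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y2 <- Y %*% R + rep(1, 20) %o% c(5, -3)
  s <- simcadx:::sammon_stress(dist(X), Y)
  expect_equal(s, simcadx:::sammon_stress(dist(X), Y2), tolerance = 1e-10)
  expect_equal(s, stress_oracle(X, Y), tolerance = 1e-12)
})

test_that("duplicate inputs are collapsed with a warning, never a division by zero", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  X <- rbind(X, X[3, ])
  expect_warning(e <- sammon_fit(X, 2), "duplicate")
  expect_equal(e$Y_train[11, ], e$Y_train[3, ])
  expect_true(is.finite(e$final_cost))
  expect_lte(e$final_cost, e$params$initial_cost + 1e-12)
})

test_that("t-SNE reduces its cost and separates well-separated clusters", {
  set.seed(9)
  X <- rbind(matrix(rnorm(30 * 4), 30, 4),
             matrix(rnorm(30 * 4, mean = 10), 30, 4))
  e <- tsne_fit(X, 2, perplexity = 15, seed = 1, iterations = 300)
  expect_gte(e$final_cost, 0)
  expect_lte(e$final_cost, e$params$initial_cost)
  km <- kmeans(e$Y_train, 2, nstart = 5)
  truth <- rep(1:2, each = 30)
  agree <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
  expect_gte(agree, 0.95)
  # determinism
  e2 <- tsne_fit(X, 2, perplexity = 15, seed = 1, iterations = 300)
  expect_identical(e$Y_train, e2$Y_train)
  expect_error(tsne_fit(X, 2, perplexity = 60), "perplexity")
})

test_that("a single XOM step matches the hand-evaluated learning rule", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  Y0 <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.5, 0.9))
  S <- matrix(c(0.75, 0.25), 1, 2)     # best match is Y0[2, ]
  D2x <- as.matrix(dist(X))^2
  sigma <- 0.8; eps <- 0.4
  got <- simcadx:::.xom_adapt_cpp(Y0, S, D2x, sigma, eps)
  h <- exp(-D2x[, 2] / (2 * sigma^2))
  expected <- Y0 + eps * h * (rep(1, 3) %o% as.vector(S) - Y0)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("XOM with zero learning rate returns its initialization", {
  set.seed(10)
  X <- matrix(rnorm(24), 8, 3)
  e <- xom_fit(X, 2, epsilon_start = 0, epsilon_end = 0, iterations = 50,
               seed = 3)
  expect_equal(e$Y_train, e$params$Y_init, tolerance = 1e-15)
})

test_that("a lone XOM point tracks the centroid of the sampling domain", {
  X <- matrix(c(1, 2), 1, 2)
  finals <- t(vapply(1:200, function(s) {
    xom_fit(X, 2, iterations = 300, seed = s)$Y_train[1, ]
  }, numeric(2)))
  se <- apply(finals, 2, sd) / sqrt(nrow(finals))
  expect_true(all(abs(colMeans(finals) - 0.5) < 3 * se))
})

test_that("XOM separates two tight input clusters in most runs", {
  set.seed(12)
  X <- rbind(matrix(rnorm(10 * 3, sd = 0.05), 10, 3),
             matrix(rnorm(10 * 3, mean = 5, sd = 0.05), 10, 3))
  truth <- rep(1:2, each = 10)
  hits <- vapply(1:20, function(s) {
    e <- xom_fit(X, 2, seed = s)
    km <- kmeans(e$Y_train, 2, nstart = 5)
    max(mean(km$cluster == truth), mean(km$cluster == 3 - truth)) >= 0.9
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
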