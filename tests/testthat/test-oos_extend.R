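test_that("Shepard weights reproduce the hand-computed two-point example", {
  # training points at distances 1 and 2 from the test point, p = 2:
  # weights 0.8 / 0.2, output (0.2, 0)
  Xtr <- rbind(c(0, 0), c(3, 0))
  Ytr <- rbind(c(0, 0), c(1, 0))
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "shepard",
                  power_p = 2)
  out <- shepard_extend(m, c(1, 0))   # distances 1 and 2
  expect_equal(as.vector(out), c(0.2, 0), tolerance = 1e-12)
})

test_that("GRBF weights reproduce the hand-computed two-point example", {
  # squared distances 0 and 2, rho = 1: weights (1, e^-1)/(1 + e^-1)
  Xtr <- rbind(c(0, 0), c(sqrt(2), 0))
  Ytr <- matrix(c(0, 1), 2, 1)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "grbf", rho = 1)
  out <- grbf_extend(m, c(0, 0))
  expect_equal(as.vector(out), exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("exact training hits return the training coordinates", {
  set.seed(1)
  Xtr <- matrix(rnorm(40), 10, 4)
  Ytr <- matrix(rnorm(20), 10, 2)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "shepard")
  out <- shepard_extend(m, Xtr[4, ])
  expect_equal(as.vector(out), Ytr[4, ], tolerance = 1e-12)
  # near-hit within the 1e-12 guard behaves like an exact hit
  out2 <- shepard_extend(m, Xtr[4, ] + 1e-14)
  expect_equal(as.vector(out2), Ytr[4, ], tolerance = 1e-10)
})

test_that("both schemes produce convex combinations of the training outputs", {
  set.seed(2)
  Xtr <- matrix(rnorm(60), 15, 4)
  Xte <- matrix(rnorm(32), 8, 4)
  # constant training outputs are reproduced exactly
  Yc <- matrix(2.5, 15, 2)
  for (sch in c("shepard", "grbf")) {
    m <- oos_mapper(X_train = Xtr, Y_train = Yc, scheme = sch)
    expect_equal(oos_extend(m, Xte), matrix(2.5, 8, 2), tolerance = 1e-12)
  }
  # outputs stay inside the bounding box of Y_train (convex hull property)
  Y <- matrix(rnorm(30), 15, 2)
  for (sch in c("shepard", "grbf")) {
    m <- oos_mapper(X_train = Xtr, Y_train = Y, scheme = sch)
    out <- oos_extend(m, Xte)
    expect_true(all(out >= min(Y) - 1e-12 & out <= max(Y) + 1e-12))
  }
})

test_that("a very wide GRBF kernel averages the training outputs", {
  set.seed(3)
  Xtr <- matrix(rnorm(40), 10, 4)
  Ytr <- matrix(rnorm(20), 10, 2)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "grbf",
                  rho = 1e6 * max(dist(Xtr)))
  out <- grbf_extend(m, rnorm(4))
  expect_equal(as.vector(out), colMeans(Ytr), tolerance = 1e-6)
})

test_that("GRBF extension is numerically stable far from the training data", {
  Xtr <- rbind(c(0, 0), c(1, 0))
  Ytr <- matrix(c(0, 1), 2, 1)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "grbf", rho = 0.1)
  out <- grbf_extend(m, c(1e4, 0))  # naive weights would underflow to 0/0
  expect_true(is.finite(out))
  expect_equal(as.vector(out), 1, tolerance = 1e-6)  # nearest point dominates
})

test_that("large Shepard powers approach nearest-neighbor assignment", {
  Xtr <- rbind(c(0, 0), c(10, 0), c(0, 10))
  Ytr <- diag(3)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "shepard",
                  power_p = 64)
  out <- shepard_extend(m, c(1, 1))
  expect_equal(as.vector(out), c(1, 0, 0), tolerance = 1e-6)
})

test_that("GRBF output varies smoothly under small input perturbations", {
  set.seed(4)
  Xtr <- matrix(rnorm(40), 10, 4)
  Ytr <- matrix(rnorm(20), 10, 2)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "grbf")
  x0 <- rnorm(4)
  base <- grbf_extend(m, x0)
  for (delta in c(1e-3, 1e-5)) {
    moved <- grbf_extend(m, x0 + delta)
    expect_lt(max(abs(moved - base)), 100 * delta)
  }
})

test_that("Shepard output varies continuously away from training points", {
  set.seed(6)
  Xtr <- matrix(rnorm(40), 10, 4)
  Ytr <- matrix(rnorm(20), 10, 2)
  m <- oos_mapper(X_train = Xtr, Y_train = Ytr, scheme = "shepard")
  x0 <- rnorm(4) + 3   # well away from the training cloud
  base <- shepard_extend(m, x0)
  for (delta in c(1e-3, 1e-5)) {
    moved <- shepard_extend(m, x0 + delta)
    expect_lt(max(abs(moved - base)), 100 * delta)
  }
})

test_that("PCA projection matches an independent linear-algebra evaluation", {
  set.seed(5)
  X <- matrix(rnorm(120), 30, 4)
  model <- pca_fit(X, 2)
  m <- oos_mapper(embedding = model, scheme = "pca_direct")
  Xte <- matrix(rnorm(20), 5, 4)
  manual <- (Xte - rep(1, 5) %o% model$mean) %*% t(model$components)
  expect_equal(oos_extend(m, Xte), manual, tolerance = 1e-12)
  # model mean maps to the origin
  expect_equal(as.vector(pca_project(model, model$mean)), c(0, 0),
               tolerance = 1e-12)
  expect_error(pca_project(model, rnorm(3)), "dimension")
})

test_that("mapper preconditions are enforced", {
  expect_error(oos_mapper(X_train = matrix(0, 0, 2),
                          Y_train = matrix(0, 0, 1), scheme = "shepard"),
               "empty")
  X <- matrix(rnorm(10), 5, 2); Y <- matrix(rnorm(5), 5, 1)
  expect_error(oos_mapper(X_train = X, Y_train = Y, scheme = "shepard",
                          power_p = 0), "power_p")
  expect_error(oos_mapper(X_train = X, Y_train = Y, scheme = "grbf",
                          rho = -1), "rho")
  expect_error(oos_mapper(scheme = "pca_direct"), "pca_model")
})
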