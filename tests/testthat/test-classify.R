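test_that("AUC matches brute-force concordant-pair counting", {
  # worked example: 3 of 4 pairs concordant
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8),
               c("healthy", "healthy", "osteoarthritic", "osteoarthritic"))
  expect_equal(r$auc, 0.75)
  # perfect separation and all-ties
  expect_equal(roc_auc(c(1, 2, 3, 4), rep(c("healthy", "osteoarthritic"),
                                          each = 2))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("healthy", "osteoarthritic"), 3))$auc,
               0.5)
  # random instances with heavy ties
  set.seed(1)
  for (k in 1:200) {
    n <- sample(5:40, 1)
    sc <- sample(0:6, n, TRUE) + 0.0
    lab <- sample(c("healthy", "osteoarthritic"), n, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(sc, lab)$auc, brute_auc(sc, lab), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("healthy", 4)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(2)
  sc <- rnorm(50)
  lab <- sample(c("healthy", "osteoarthritic"), 50, TRUE)
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(exp(sc), lab)$auc, a)
  expect_equal(roc_auc(5 * sc - 3, lab)$auc, a)
})

test_that("ROC curve endpoints and monotonicity are correct", {
  set.seed(3)
  r <- roc_auc(rnorm(30), sample(c("healthy", "osteoarthritic"), 30, TRUE,
                                 prob = c(0.5, 0.5)), curve = TRUE)
  cv <- r$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
})

test_that("patient split honors both patient constraints", {
  d <- generate_feature_dataset(5, 250, 9, 2, seed = 3)
  plan <- make_patient_split(d, n_per_patient = 200, seed = 11)
  expect_length(plan$test_rows, 400L)
  expect_length(plan$train_rows, 600L)
  # exactly one test patient per class
  test_pat <- unique(d$patient_ids[plan$test_rows])
  expect_setequal(test_pat, plan$test_patients)
  expect_setequal(substr(sort(test_pat), 1, 1), c("H", "O"))
  # constraint 1: patient-disjoint train/test
  expect_length(intersect(unique(d$patient_ids[plan$train_rows]), test_pat), 0L)
  # constraint 2: equal row counts per patient
  counts <- table(d$patient_ids[c(plan$train_rows, plan$test_rows)])
  expect_true(all(counts == 200L))
  # no row duplication when patients are large enough
  expect_false(anyDuplicated(c(plan$train_rows, plan$test_rows)) > 0)
  # determinism
  plan2 <- make_patient_split(d, n_per_patient = 200, seed = 11)
  expect_identical(plan, plan2)
})

test_that("undersized patients are resampled with replacement with a warning", {
  d <- generate_feature_dataset(4, 30, 5, 1, seed = 5)
  expect_warning(plan <- make_patient_split(d, n_per_patient = 50, seed = 1),
                 "replacement")
  counts <- table(d$patient_ids[c(plan$train_rows, plan$test_rows)])
  expect_true(all(counts == 50L))
})

test_that("configuration compatibility rules are enforced", {
  expect_error(experiment_config("pca", target_dim = 2,
                                 oos_scheme = "shepard"), "incompatible")
  expect_error(experiment_config("sammon", target_dim = 2,
                                 oos_scheme = "pca_direct"), "incompatible")
  expect_error(experiment_config("pca"), "target_dim")
  cfg <- experiment_config("tsne", target_dim = 3)
  expect_identical(cfg$oos_scheme, "shepard")
  expect_identical(experiment_config("none")$oos_scheme, "none")
})

test_that("indistinguishable classes score near-chance AUC", {
  d <- generate_feature_dataset(5, 120, 9, 0, seed = 4)
  cfg <- experiment_config("none", n_iterations = 10, n_per_patient = 100,
                           master_seed = 21)
  r <- run_experiment(d, cfg)
  expect_gt(r$mean, 0.35)
  expect_lt(r$mean, 0.65)
})

test_that("well-separated classes are classified nearly perfectly", {
  d <- generate_feature_dataset(5, 120, 9, 5, seed = 4)
  for (red in list(c("none", NA), c("pca", 2))) {
    cfg <- experiment_config(red[1],
                             target_dim = if (is.na(red[2])) NULL
                                          else as.integer(red[2]),
                             n_iterations = 3, n_per_patient = 100,
                             master_seed = 5)
    r <- run_experiment(d, cfg)
    expect_gt(r$mean, 0.95)
  }
})

test_that("experiments are reproducible and bookkeeping is exact", {
  d <- generate_feature_dataset(5, 80, 9, 2, seed = 6)
  cfg <- experiment_config("mi", target_dim = 2, n_iterations = 4,
                           n_per_patient = 60, master_seed = 7)
  r1 <- run_experiment(d, cfg)
  r2 <- run_experiment(d, cfg)
  expect_identical(r1$aucs, r2$aucs)
  expect_length(r1$aucs, 4L)
  expect_true(all(r1$aucs >= 0 & r1$aucs <= 1))
  expect_equal(r1$mean, mean(r1$aucs))
  expect_equal(r1$sd, sd(r1$aucs))
})

test_that("provenance-free data triggers the pseudo-patient fallback", {
  d <- generate_feature_dataset(2, 150, 5, 3, seed = 8)
  bare <- labeled_feature_set(d$features, as.character(d$labels),
                              rep("unknown", nrow(d$features)),
                              unknown_patient = TRUE)
  cfg <- experiment_config("none", n_iterations = 2, n_per_patient = 40,
                           master_seed = 9)
  r <- run_experiment(bare, cfg)
  expect_match(r$notes, "pseudo-patients", all = FALSE)
  expect_length(r$aucs, 2L)
})

test_that("permuted labels calibrate to chance over repeated iterations", {
  d <- generate_feature_dataset(5, 120, 9, 4, seed = 10)
  # permute labels within the patient blocks' label structure: relabel
  # patients so the feature/label association is broken but the patient
  # structure stays intact
  with_seed <- simcadx:::with_seed
  perm <- with_seed(31, sample(nrow(d$features)))
  dperm <- labeled_feature_set(d$features[perm, ], as.character(d$labels),
                               d$patient_ids)
  cfg <- experiment_config("none", n_iterations = 10, n_per_patient = 100,
                           master_seed = 13)
  r <- run_experiment(dperm, cfg)
  expect_gt(r$mean, 0.35); expect_lt(r$mean, 0.65)
})
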