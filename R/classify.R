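#' ROC analysis of continuous classifier scores
#'
#' Area under the ROC curve via the rank (Mann-Whitney) construction: the
#' probability that a randomly chosen osteoarthritic score exceeds a
#' randomly chosen healthy score, with ties counting one half. Equivalent
#' to trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric classifier outputs (higher = more osteoarthritic).
#' @param labels class labels; both classes must be present.
#' @param curve if `TRUE`, also return the ROC curve points.
#' @return An object of class `roc_result`: list with `auc`, `n_pos`,
#'   `n_neg` and optionally `curve` (data.frame of threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels, curve = FALSE) {
  scores <- as.numeric(scores)
  labels <- as.factor(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("both classes must be present")
  pos_level <- if ("osteoarthritic" %in% levels(labels)) "osteoarthritic"
               else levels(labels)[2L]
  pos <- labels == pos_level
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out <- list(auc = auc, n_pos = n_pos, n_neg = n_neg,
              positive = pos_level)
  if (curve) {
    th <- c(Inf, sort(unique(scores), decreasing = TRUE))
    out$curve <- data.frame(
      threshold = th,
      fpr = vapply(th, function(t) sum(scores[!pos] >= t) / n_neg, 0),
      tpr = vapply(th, function(t) sum(scores[pos] >= t) / n_pos, 0)
    )
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Patient-constrained train/test split
#'
#' Implements the two patient constraints of the evaluation protocol:
#' (1) rows from the same patient never appear in both training and test
#' sets, and (2) every patient contributes exactly the same number of rows.
#' Each patient's rows are uniformly subsampled to `n_per_patient` (with
#' replacement, and a warning, if a patient has fewer rows), and one
#' randomly chosen healthy patient plus one randomly chosen osteoarthritic
#' patient form the test set.
#'
#' @param data a [labeled_feature_set()] with at least one patient per
#'   class; every patient's rows must carry a single label.
#' @param n_per_patient rows kept per patient (default 200).
#' @param seed integer seed.
#' @return An object of class `split_plan`: list with `test_patients`
#'   (one healthy + one osteoarthritic id), `train_rows`, `test_rows`
#'   (row indices into `data`), `rows_per_patient` and `seed`.
#' @export
make_patient_split <- function(data, n_per_patient = 200L, seed = NULL) {
  stopifnot(inherits(data, "labeled_feature_set"))
  pids <- data$patient_ids
  patients <- sort(unique(pids))
  plab <- vapply(patients, function(p) {
    u <- unique(as.character(data$labels[pids == p]))
    if (length(u) != 1L) stop("patient '", p, "' carries mixed labels")
    u
  }, "")
  healthy <- patients[plab == "healthy"]
  oa <- patients[plab == "osteoarthritic"]
  if (length(healthy) < 1L || length(oa) < 1L) {
    stop("need at least one patient in each class")
  }
  with_seed(seed, {
    test_patients <- c(healthy[sample.int(length(healthy), 1L)],
                       oa[sample.int(length(oa), 1L)])
    picked <- lapply(patients, function(p) {
      rows <- which(pids == p)
      if (length(rows) >= n_per_patient) {
        sample(rows, n_per_patient)
      } else {
        warning("patient '", p, "' has ", length(rows), " rows < ",
                n_per_patient, "; sampling with replacement")
        sample(rows, n_per_patient, replace = TRUE)
      }
    })
    names(picked) <- patients
    is_test <- patients %in% test_patients
    structure(
      list(test_patients = test_patients,
           train_rows = unlist(picked[!is_test], use.names = FALSE),
           test_rows = unlist(picked[is_test], use.names = FALSE),
           rows_per_patient = n_per_patient,
           seed = seed),
      class = "split_plan"
    )
  })
}

#' Experiment configuration
#'
#' Bundles a feature reduction strategy, target dimension, out-of-sample
#' extension scheme and tuning grids for the repeated patient-constrained
#' evaluation protocol.
#'
#' @param reduction one of `"none"`, `"pca"`, `"sammon"`, `"tsne"`,
#'   `"xom"`, `"mi"`.
#' @param target_dim reduced dimension (ignored for `"none"`; the study
#'   used 2, 3 and 5, with 9 for the unreduced feature set).
#' @param oos_scheme `"shepard"`, `"grbf"`, `"pca_direct"` or `"none"`;
#'   defaults to the scheme matching the reduction (`pca_direct` for PCA,
#'   `shepard` for the non-linear embeddings, `none` for `none`/`mi`).
#' @param n_iterations number of protocol repetitions (default 50).
#' @param n_per_patient rows subsampled per patient (default 200).
#' @param inner_frac inner training fraction of the 70/30 validation split.
#' @param svr_cost_grid SVR cost values searched in the inner loop.
#' @param svr_epsilon SVR epsilon-tube width.
#' @param svr_tolerance libSVM convergence tolerance; the default 0.01 is
#'   looser than libSVM's 0.001 — ranking by the continuous SVR output is
#'   insensitive to the final KKT digits, and convergence at large cost
#'   values is much faster.
#' @param tuning_grids named list of method hyperparameter grids:
#'   `power_p` (Shepard), `rho_factor` (GRBF width as a multiple of the
#'   median training distance), `perplexity` (t-SNE), `sigma_frac` (XOM
#'   neighborhood start as a fraction of the data diameter).
#' @param embed_control iteration budgets for the embedding fits
#'   (`sammon_iterations`, `tsne_iterations`, `xom_iterations`).
#' @param master_seed seed from which all per-iteration seeds derive.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(reduction = c("none", "pca", "sammon", "tsne",
                                            "xom", "mi"),
                              target_dim = NULL, oos_scheme = NULL,
                              n_iterations = 50L, n_per_patient = 200L,
                              inner_frac = 0.7,
                              svr_cost_grid = 10^(-3:3), svr_epsilon = 0.1,
                              svr_tolerance = 0.01,
                              tuning_grids = list(),
                              embed_control = list(),
                              master_seed = 1L) {
  reduction <- match.arg(reduction)
  if (reduction == "none") target_dim <- NA_integer_
  else {
    if (is.null(target_dim)) stop("'target_dim' is required for reduction '",
                                  reduction, "'")
    target_dim <- as.integer(target_dim)
    if (target_dim < 1L) stop("'target_dim' must be >= 1")
  }
  default_scheme <- switch(reduction,
                           none = "none", mi = "none", pca = "pca_direct",
                           "shepard")
  oos_scheme <- oos_scheme %||% default_scheme
  ok <- switch(reduction,
               none = "none", mi = "none", pca = "pca_direct",
               c("shepard", "grbf"))
  if (!oos_scheme %in% ok) {
    stop("oos_scheme '", oos_scheme, "' is incompatible with reduction '",
         reduction, "'")
  }
  grids <- utils::modifyList(
    list(power_p = c(1, 2, 4), rho_factor = c(0.5, 1, 2),
         perplexity = c(10, 30, 50), sigma_frac = c(0.05, 0.1, 0.2)),
    tuning_grids)
  ec <- utils::modifyList(
    list(sammon_iterations = 200L, tsne_iterations = 1000L,
         xom_iterations = NULL),
    embed_control)
  stopifnot(inner_frac > 0, inner_frac < 1, n_iterations >= 1L,
            all(svr_cost_grid > 0))
  structure(
    list(reduction = reduction, target_dim = target_dim,
         oos_scheme = oos_scheme, n_iterations = as.integer(n_iterations),
         n_per_patient = as.integer(n_per_patient), inner_frac = inner_frac,
         svr_cost_grid = svr_cost_grid, svr_epsilon = svr_epsilon,
         svr_tolerance = svr_tolerance,
         tuning_grids = grids, embed_control = ec,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

# Linear-kernel epsilon-SVR (libSVM). Targets: healthy = 0,
# osteoarthritic = 1; ranking uses the raw continuous output. Inputs are
# standardized from the training rows (libSVM's recommended practice).
svr_fit <- function(Z, labels, cost, epsilon, tolerance = 0.01) {
  y <- as.numeric(labels == "osteoarthritic")
  suppressWarnings(
    e1071::svm(x = as.matrix(Z), y = y, type = "eps-regression",
               kernel = "linear", cost = cost, epsilon = epsilon,
               scale = TRUE, tolerance = tolerance)
  )
}

# Stratified inner split: inner_frac of each class for tuning-training,
# the rest for validation.
make_inner_split <- function(labels, inner_frac, seed) {
  with_seed(seed, {
    idx_tr <- unlist(lapply(levels(labels), function(lv) {
      rows <- which(labels == lv)
      sample(rows, max(1L, round(inner_frac * length(rows))))
    }), use.names = FALSE)
    idx_val <- setdiff(seq_along(labels), idx_tr)
    if (length(unique(labels[idx_val])) < 2L ||
        length(unique(labels[idx_tr])) < 2L) {
      stop("degenerate single-class inner split")
    }
    list(train = sort(idx_tr), val = sort(idx_val))
  })
}

# Fit the configured feature reduction on the training rows only.
# Returns Z_train (reduced training coordinates), an `extend(X_rows_idx,
# X_new, params)` closure mapping new points using only the given training
# rows, the per-candidate hyperparameter grid, and the fitted artifacts.
fit_reduction <- function(train, config, embed_seed) {
  X <- train$features
  d <- config$target_dim
  g <- config$tuning_grids
  oos_grid <- switch(config$oos_scheme,
                     shepard = data.frame(power_p = g$power_p),
                     grbf = data.frame(rho_factor = g$rho_factor),
                     data.frame(dummy = 0))
  make_extend <- function(emb) {
    function(rows, X_new, params) {
      Xi <- emb$X_train[rows, , drop = FALSE]
      Yi <- emb$Y_train[rows, , drop = FALSE]
      if (config$oos_scheme == "shepard") {
        oos_extend(oos_mapper(X_train = Xi, Y_train = Yi, scheme = "shepard",
                              power_p = params$power_p), X_new)
      } else {
        rho <- params$rho_factor * stats::median(dist(Xi))
        oos_extend(oos_mapper(X_train = Xi, Y_train = Yi, scheme = "grbf",
                              rho = rho), X_new)
      }
    }
  }
  switch(config$reduction,
    none = list(
      Z = X, grid = data.frame(dummy = 0),
      extend = function(rows, X_new, params) X_new,
      artifacts = list()),
    mi = {
      sel <- select_top_features(train, d)
      list(Z = X[, sel, drop = FALSE], grid = data.frame(dummy = 0),
           extend = function(rows, X_new, params) X_new[, sel, drop = FALSE],
           artifacts = list(selected = as.integer(sel),
                            scores = attr(sel, "scores")))
    },
    pca = {
      model <- pca_fit(X, d)
      list(Z = model$Y_train, grid = data.frame(dummy = 0),
           extend = function(rows, X_new, params) pca_project(model, X_new),
           artifacts = list(pca = model))
    },
    sammon = {
      emb <- sammon_fit(X, d, iterations = config$embed_control$sammon_iterations)
      list(Z = emb$Y_train, grid = oos_grid, extend = make_extend(emb),
           artifacts = list(embedding = emb))
    },
    tsne = {
      perp <- pmin(g$perplexity, nrow(X) - 1L)
      perp <- unique(perp)
      embs <- lapply(perp, function(pp) {
        tsne_fit(X, d, perplexity = pp, seed = embed_seed,
                 iterations = config$embed_control$tsne_iterations)
      })
      grid <- merge(data.frame(perplexity = perp), oos_grid)
      list(Z = NULL, grid = grid, embeddings = embs, perp_values = perp,
           extend_for = function(pp) make_extend(embs[[match(pp, perp)]]),
           artifacts = list(embeddings = embs))
    },
    xom = {
      fracs <- g$sigma_frac
      embs <- lapply(fracs, function(fr) {
        diam <- max(dist(X))
        xom_fit(X, d, sigma_start = fr * diam, sigma_end = 0.05 * fr * diam,
                iterations = config$embed_control$xom_iterations,
                seed = embed_seed)
      })
      grid <- merge(data.frame(sigma_frac = fracs), oos_grid)
      list(Z = NULL, grid = grid, embeddings = embs, perp_values = fracs,
           extend_for = function(fr) make_extend(embs[[match(fr, fracs)]]),
           artifacts = list(embeddings = embs))
    }
  )
}

#' One iteration of the patient-constrained evaluation protocol
#'
#' Executes a single protocol iteration: (1) draw a patient-constrained
#' split; (2) fit the configured feature reduction on the training rows
#' only; (3) grid-search SVR cost jointly with the method and extension
#' hyperparameters on a stratified 70/30 inner split of the training set,
#' scoring each candidate by validation AUC (validation points are mapped
#' by out-of-sample extension from the inner-training rows); (4) refit the
#' winning SVR on the full training set; (5) extend the test rows into the
#' embedding and score the test AUC from the continuous SVR output.
#'
#' Test rows never participate in reduction fitting, feature ranking,
#' hyperparameter selection or SVR fitting; they enter only extension and
#' scoring.
#'
#' @param data a [labeled_feature_set()] with patient provenance.
#' @param config an [experiment_config()].
#' @param seed iteration seed (drives the split, the inner split and any
#'   stochastic embedding).
#' @param detail if `TRUE`, return the fitted artifacts alongside the AUC.
#' @return The test AUC (numeric scalar), or with `detail = TRUE` a list
#'   with `auc`, `winner`, `plan`, `reduction` (fitted artifacts) and
#'   `svr_model`.
#' @export
run_cv_iteration <- function(data, config, seed, detail = FALSE) {
  stopifnot(inherits(data, "labeled_feature_set"),
            inherits(config, "experiment_config"))
  sds <- derive_seeds(seed, 3L)
  plan <- make_patient_split(data, config$n_per_patient, sds[1])
  tr <- subset_rows(data, plan$train_rows)
  te <- subset_rows(data, plan$test_rows)
  inner <- make_inner_split(tr$labels, config$inner_frac, sds[2])
  red <- fit_reduction(tr, config, embed_seed = sds[3])

  grid <- red$grid
  best <- list(score = -Inf)
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    if (!is.null(red$extend_for)) {
      key <- params[[1L]]             # perplexity or sigma_frac
      extend <- red$extend_for(key)
      Zfull <- red$embeddings[[match(key, red$perp_values)]]$Y_train
    } else {
      extend <- red$extend
      Zfull <- red$Z
    }
    Z_in <- Zfull[inner$train, , drop = FALSE]
    Z_val <- extend(inner$train, tr$features[inner$val, , drop = FALSE],
                    params)
    for (cost in config$svr_cost_grid) {
      fit <- svr_fit(Z_in, tr$labels[inner$train], cost, config$svr_epsilon,
                     config$svr_tolerance)
      sc <- predict(fit, as.matrix(Z_val))
      val_auc <- roc_auc(sc, tr$labels[inner$val])$auc
      if (val_auc > best$score) {
        best <- list(score = val_auc, cost = cost, params = params,
                     extend = extend, Zfull = Zfull)
      }
    }
  }

  final_fit <- svr_fit(best$Zfull, tr$labels, best$cost, config$svr_epsilon,
                       config$svr_tolerance)
  Z_test <- best$extend(seq_len(nrow(tr$features)), te$features, best$params)
  scores <- predict(final_fit, as.matrix(Z_test))
  auc <- roc_auc(scores, te$labels)$auc
  if (!detail) return(auc)
  list(auc = auc,
       winner = c(list(cost = best$cost, val_auc = best$score), best$params),
       plan = plan,
       reduction = red$artifacts,
       svr_model = final_fit,
       test_scores = as.numeric(scores),
       test_labels = te$labels)
}

#' Repeated patient-constrained evaluation
#'
#' Repeats [run_cv_iteration()] `n_iterations` times (default 50) with
#' independent seeds derived from the configuration's master seed, yielding
#' the AUC distribution for one (reduction, dimension) configuration. Data
#' without patient provenance (`unknown_patient`) is first partitioned into
#' seeded pseudo-patients (2 healthy, 3 osteoarthritic) and the deviation
#' is recorded on the result.
#'
#' @param data a [labeled_feature_set()].
#' @param config an [experiment_config()].
#' @param keep_winners record each iteration's winning hyperparameters.
#' @return An object of class `auc_distribution`: list with `aucs`
#'   (length `n_iterations`), `mean`, `sd`, `config`, `iteration_seeds`,
#'   `winners` and `notes`.
#' @export
run_experiment <- function(data, config, keep_winners = FALSE) {
  stopifnot(inherits(data, "labeled_feature_set"),
            inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$master_seed, config$n_iterations + 1L)
  notes <- character(0)
  if (data$unknown_patient) {
    data <- assign_pseudo_patients(data, seed = seeds[config$n_iterations + 1L])
    notes <- c(notes, "patient provenance unknown: seeded pseudo-patients (2 healthy, 3 osteoarthritic) substituted")
  }
  winners <- if (keep_winners) vector("list", config$n_iterations) else NULL
  aucs <- numeric(config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    if (keep_winners) {
      res <- run_cv_iteration(data, config, seeds[i], detail = TRUE)
      aucs[i] <- res$auc
      winners[[i]] <- res$winner
    } else {
      aucs[i] <- run_cv_iteration(data, config, seeds[i])
    }
  }
  structure(
    list(aucs = aucs, mean = mean(aucs), sd = sd(aucs), config = config,
         iteration_seeds = seeds[seq_len(config$n_iterations)],
         winners = winners, notes = notes),
    class = "auc_distribution"
  )
}

#' @export
print.auc_distribution <- function(x, ...) {
  dim_txt <- if (is.na(x$config$target_dim)) "9 (unreduced)"
             else as.character(x$config$target_dim)
  cat(sprintf("AUC over %d iterations: %.3f +/- %.3f  [%s, dim %s, oos %s]\n",
              length(x$aucs), x$mean, x$sd, x$config$reduction, dim_txt,
              x$config$oos_scheme))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
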