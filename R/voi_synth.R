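#' Generate a synthetic cartilage volume of interest
#'
#' Builds a cubic gray-level volume emulating the texture contrast between
#' healthy and osteoarthritic cartilage in the radial zone: chondrocyte
#' lacunae appear as dark ellipsoidal inclusions on a brighter matrix.
#' Healthy volumes place inclusion centers in vertical columns (aligned along
#' the z axis, emulating Benninghoff-arch chondrocyte alignment); diseased
#' volumes scatter the inclusion centers uniformly at random (disorganized
#' clustering). Additive Gaussian background noise is applied last.
#'
#' @param label `"healthy"` or `"osteoarthritic"`.
#' @param side voxels per cube edge (default 25).
#' @param n_inclusions number of ellipsoidal inclusions (default 6).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed; identical arguments give an identical volume.
#' @param patient_id identifier carried through feature extraction.
#' @param background background gray level.
#' @param amplitude peak darkening of an inclusion relative to background.
#' @param semi_axes ellipsoid semi-axes (x, y, z) in voxels; inclusions are
#'   smooth Gaussian-profile pits rather than hard-edged voids.
#' @param n_columns number of columns used for the healthy alignment
#'   geometry; defaults to `ceiling(n_inclusions / 4)`.
#'
#' @return An object of class `voi`: list with `intensities` (3-D array),
#'   `side_length`, `label`, `patient_id`. The inclusion centers actually
#'   used are attached as `attr(, "centers")` (one row per inclusion,
#'   columns x, y, z) for diagnostic use.
#' @examples
#' v <- generate_voi("healthy", side = 15, n_inclusions = 4, noise_sd = 0.5,
#'                   seed = 1)
#' dim(v$intensities)
#' @export
generate_voi <- function(label = c("healthy", "osteoarthritic"),
                         side = 25L, n_inclusions = 6L, noise_sd = 1,
                         seed = NULL, patient_id = "synthetic",
                         background = 100, amplitude = 40,
                         semi_axes = c(1.5, 1.5, 2.5),
                         n_columns = NULL) {
  label <- match.arg(label)
  side <- as.integer(side)
  if (length(side) != 1L || side < 5L) stop("'side' must be a single integer >= 5")
  if (n_inclusions < 0L) stop("'n_inclusions' must be >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("'semi_axes' must be three positive values")
  }

  with_seed(seed, {
    vol <- array(background, dim = c(side, side, side))
    centers <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    if (n_inclusions > 0L) {
      margin <- max(semi_axes)
      lo <- 1 + margin
      hi <- side - margin
      if (hi <= lo) { lo <- 1; hi <- side }
      if (label == "healthy") {
        # columns: few (x, y) positions, centers stacked evenly in z
        ncol_use <- n_columns %||% max(1L, ceiling(n_inclusions / 4))
        colxy <- cbind(runif(ncol_use, lo, hi), runif(ncol_use, lo, hi))
        assign_col <- rep_len(seq_len(ncol_use), n_inclusions)
        z <- numeric(n_inclusions)
        for (cc in seq_len(ncol_use)) {
          members <- which(assign_col == cc)
          zz <- seq(lo, hi, length.out = length(members) + 2L)[-c(1L, length(members) + 2L)]
          z[members] <- zz + runif(length(members), -0.5, 0.5)
        }
        centers <- cbind(x = colxy[assign_col, 1], y = colxy[assign_col, 2],
                         z = z)
      } else {
        centers <- cbind(x = runif(n_inclusions, lo, hi),
                         y = runif(n_inclusions, lo, hi),
                         z = runif(n_inclusions, lo, hi))
      }
      ax <- seq_len(side)
      for (k in seq_len(n_inclusions)) {
        dx2 <- ((ax - centers[k, 1]) / semi_axes[1])^2
        dy2 <- ((ax - centers[k, 2]) / semi_axes[2])^2
        dz2 <- ((ax - centers[k, 3]) / semi_axes[3])^2
        q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
        vol <- vol - amplitude * exp(-q / 2)
      }
    }
    if (noise_sd > 0) {
      vol <- vol + array(rnorm(side^3, sd = noise_sd), dim = dim(vol))
    }
    structure(
      list(intensities = vol, side_length = side, label = label,
           patient_id = as.character(patient_id)),
      centers = centers,
      class = "voi"
    )
  })
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("VOI %d^3 voxels, label: %s, patient: %s\n",
              x$side_length, x$label, x$patient_id))
  invisible(x)
}

#' Generate a synthetic labeled feature dataset
#'
#' Feature-level stand-in for SIM-derived quantile vectors: each class draws
#' from a multivariate Gaussian with identity covariance, and the class mean
#' vectors differ by `class_separation` along the all-ones direction. Rows
#' are partitioned into patients (`floor(n_patients/2)` healthy, the rest
#' osteoarthritic), each contributing exactly `n_per_patient` rows.
#'
#' With `sort_rows = TRUE` (default) each row is sorted ascending so the
#' vectors satisfy the non-decreasing structure of a quantile feature
#' vector. Because the class shift is constant across coordinates, sorting
#' commutes with it and class separation is preserved exactly.
#'
#' @param n_patients total number of patients (>= 2, at least one per class).
#' @param n_per_patient rows per patient.
#' @param dim feature dimension (default 9).
#' @param class_separation Euclidean distance between class means.
#' @param seed integer seed.
#' @param sort_rows sort each feature vector ascending (default `TRUE`).
#' @return A [labeled_feature_set()].
#' @examples
#' d <- generate_feature_dataset(5, 200, 9, 2, seed = 3)
#' table(d$labels)
#' @export
generate_feature_dataset <- function(n_patients, n_per_patient, dim = 9L,
                                     class_separation = 1, seed = NULL,
                                     sort_rows = TRUE) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("need at least one patient per class (n_patients >= 2)")
  if (n_per_patient < 1L) stop("'n_per_patient' must be >= 1")
  if (dim < 1L) stop("'dim' must be >= 1")
  if (!is.finite(class_separation) || class_separation < 0) {
    stop("'class_separation' must be >= 0")
  }
  n_healthy <- n_patients %/% 2L
  n_oa <- n_patients - n_healthy
  pat <- c(paste0("H", seq_len(n_healthy)), paste0("O", seq_len(n_oa)))
  pat_label <- rep(c("healthy", "osteoarthritic"), c(n_healthy, n_oa))
  shift <- class_separation / sqrt(dim)   # per-coordinate class shift

  with_seed(seed, {
    n <- n_patients * n_per_patient
    X <- matrix(rnorm(n * dim), nrow = n, ncol = dim)
    labels <- rep(pat_label, each = n_per_patient)
    X[labels == "osteoarthritic", ] <-
      X[labels == "osteoarthritic", , drop = FALSE] + shift
    if (sort_rows) X <- t(apply(X, 1, sort))
    colnames(X) <- paste0("f", seq_len(dim))
    labeled_feature_set(X, labels, rep(pat, each = n_per_patient))
  })
}

#' Partition rows of a provenance-free dataset into pseudo-patients
#'
#' When a feature set lacks patient identifiers, the patient-constrained
#' protocol cannot run as stated. This fallback partitions healthy rows into
#' `n_healthy` and diseased rows into `n_oa` seeded random groups, emulating
#' the study's 2 healthy / 3 osteoarthritic donors by default. The
#' substitution is recorded on the returned object (`unknown_patient` stays
#' `TRUE`).
#'
#' @param data a [labeled_feature_set()].
#' @param n_healthy,n_oa number of pseudo-patients per class.
#' @param seed integer seed.
#' @return A [labeled_feature_set()] with synthetic patient identifiers.
#' @export
assign_pseudo_patients <- function(data, n_healthy = 2L, n_oa = 3L, seed = NULL) {
  stopifnot(inherits(data, "labeled_feature_set"))
  if (n_healthy < 1L || n_oa < 1L) stop("need >= 1 pseudo-patient per class")
  with_seed(seed, {
    ids <- character(nrow(data$features))
    h <- which(data$labels == "healthy")
    o <- which(data$labels == "osteoarthritic")
    if (length(h) < n_healthy || length(o) < n_oa) {
      stop("not enough rows to form the requested pseudo-patients")
    }
    ids[h] <- paste0("pseudoH", sample(rep_len(seq_len(n_healthy), length(h))))
    ids[o] <- paste0("pseudoO", sample(rep_len(seq_len(n_oa), length(o))))
    out <- labeled_feature_set(data$features, as.character(data$labels), ids,
                               unknown_patient = TRUE)
    out
  })
}
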