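#' Scaling index transform of a volume of interest
#'
#' Assigns every voxel a local scaling index. Each voxel is treated as a 4-D
#' point \eqn{(x, y, z, s \cdot g)} combining its three spatial coordinates
#' (unit voxel spacing) with its gray level \eqn{g} scaled by the intensity
#' scaling constant \eqn{s}. The index at voxel \eqn{i} for neighborhood
#' radius \eqn{r} is
#' \deqn{\alpha_i = 2 \frac{\sum_j (d_{ij}/r)^2 e^{-(d_{ij}/r)^2}}
#'                        {\sum_j e^{-(d_{ij}/r)^2}},}
#' with \eqn{d_{ij}} the 4-D Euclidean distance and the sum over all voxels
#' of the volume, self term included (it contributes 0 to the numerator and
#' 1 to the denominator). Low \eqn{\alpha} marks locally flat/point-like
#' structure, higher \eqn{\alpha} space-filling structure.
#'
#' Exact evaluation is quadratic in the voxel count. By default neighbors
#' whose *spatial* distance exceeds `cutoff_mult * radius_r` are omitted;
#' their Gaussian weights are at most \eqn{e^{-c^2}} (\eqn{c} =
#' `cutoff_mult`), and a per-voxel absolute error bound on \eqn{\alpha} is
#' computed and reported (`error_bound`). With the default `cutoff_mult = 4`
#' the error is typically below \eqn{10^{-4}} — negligible against the
#' spread of the \eqn{\alpha} distribution.
#'
#' @param voi a [generate_voi()] object or a 3-D numeric array.
#' @param radius_r Gaussian neighborhood radius in voxel units (default 1).
#' @param intensity_scale scaling constant coupling gray level to the
#'   spatial axes (default 1: one gray-level unit equals one voxel edge).
#' @param cutoff_mult spatial truncation radius in units of `radius_r`;
#'   `Inf` requests exact all-pairs evaluation.
#' @param normalize_intensity if `TRUE`, min-max normalize intensities to
#'   `[0, 1]` before the transform (off by default; raw units are used as
#'   given).
#' @return An object of class `alpha_map`: list with `alpha` (3-D array,
#'   same shape as the input), `radius_r`, `intensity_scale`, `truncated`,
#'   and `error_bound` (max over voxels of the documented absolute bound;
#'   0 in exact mode).
#' @examples
#' v <- generate_voi("healthy", side = 10, n_inclusions = 2, noise_sd = 0.5,
#'                   seed = 1)
#' am <- scaling_index_transform(v, radius_r = 1)
#' range(am$alpha)
#' @export
scaling_index_transform <- function(voi, radius_r = 1, intensity_scale = 1,
                                    cutoff_mult = 4,
                                    normalize_intensity = FALSE) {
  g <- if (inherits(voi, "voi")) voi$intensities else voi
  if (!is.array(g) || length(dim(g)) != 3L) {
    stop("'voi' must be a voi object or a 3-D array")
  }
  if (length(g) == 0L) stop("empty VOI")
  if (anyNA(g) || !all(is.finite(g))) stop("VOI intensities must be finite")
  if (!is.finite(radius_r) || radius_r <= 0) stop("'radius_r' must be > 0")
  if (!(is.finite(cutoff_mult) && cutoff_mult > 0) && !is.infinite(cutoff_mult)) {
    stop("'cutoff_mult' must be positive or Inf")
  }
  if (isTRUE(normalize_intensity)) {
    rng <- range(g)
    g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  }
  res <- .sim_alpha_cpp(as.double(g), dim(g), radius_r, intensity_scale,
                        if (is.infinite(cutoff_mult)) -1 else cutoff_mult)
  structure(
    list(alpha = array(res$alpha, dim = dim(g)),
         radius_r = radius_r,
         intensity_scale = intensity_scale,
         truncated = is.finite(cutoff_mult),
         error_bound = max(res$error_bound)),
    class = "alpha_map"
  )
}

#' @export
print.alpha_map <- function(x, ...) {
  cat(sprintf("Scaling index map %s, r = %g%s\n",
              paste(dim(x$alpha), collapse = "x"), x$radius_r,
              if (x$truncated)
                sprintf(" (truncated, |err| <= %.3g)", x$error_bound)
              else " (exact)"))
  invisible(x)
}

#' Quantile summary of a scaling index distribution
#'
#' Summarizes the flattened distribution of per-voxel scaling indices by its
#' empirical quantiles — by default the nine deciles (10th, 20th, ..., 90th),
#' giving the 9-D geometric feature vector used for classification.
#' Quantiles use linear interpolation between order statistics (type 7).
#'
#' @param alpha_map an [scaling_index_transform()] result.
#' @param levels strictly increasing quantile levels in (0, 1).
#' @return An object of class `sim_feature_vector`: a named numeric vector
#'   (non-decreasing) with attributes `levels`, `radius_r` and
#'   `quantile_type`.
#' @export
quantile_features <- function(alpha_map, levels = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(alpha_map, "alpha_map"))
  if (length(levels) == 0L) stop("'levels' must be non-empty")
  if (any(levels <= 0) || any(levels >= 1) || is.unsorted(levels, strictly = TRUE)) {
    stop("'levels' must be strictly increasing within (0, 1)")
  }
  q <- quantile(as.vector(alpha_map$alpha), probs = levels, names = FALSE,
                type = 7)
  names(q) <- paste0("q", round(100 * levels))
  structure(q, levels = levels, radius_r = alpha_map$radius_r,
            quantile_type = 7L, class = c("sim_feature_vector", "numeric"))
}

#' Extract SIM quantile features from a set of volumes
#'
#' Runs the scaling index transform on every volume and stacks the quantile
#' feature vectors into a labeled feature set, carrying each volume's label
#' and patient identifier through.
#'
#' @param vois list of [generate_voi()] objects (all the same shape).
#' @param radius_r neighborhood radius (default 1, the study's setting).
#' @param levels quantile levels (default the nine deciles).
#' @param ... passed to [scaling_index_transform()] (`intensity_scale`,
#'   `cutoff_mult`, `normalize_intensity`).
#' @return A [labeled_feature_set()] with one row per volume.
#' @export
extract_features <- function(vois, radius_r = 1,
                             levels = seq(0.1, 0.9, by = 0.1), ...) {
  stopifnot(length(vois) >= 1L, all(vapply(vois, inherits, TRUE, "voi")))
  shapes <- vapply(vois, function(v) paste(dim(v$intensities), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("all VOIs must share the same shape")
  rows <- t(vapply(vois, function(v) {
    as.numeric(quantile_features(
      scaling_index_transform(v, radius_r = radius_r, ...), levels = levels))
  }, numeric(length(levels))))
  colnames(rows) <- paste0("q", round(100 * levels))
  labeled_feature_set(rows,
                      vapply(vois, `[[`, "", "label"),
                      vapply(vois, `[[`, "", "patient_id"))
}
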