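#' Labeled feature set
#'
#' The common container for feature-level data: an `N x D` numeric matrix of
#' feature vectors, a class label per row (`healthy` or `osteoarthritic`) and
#' a patient identifier per row. All supervised machinery in this package
#' (patient-constrained splitting, mutual-information ranking, embedding and
#' classification) consumes this container.
#'
#' @param features numeric matrix, one feature vector per row.
#' @param labels character or factor of class labels, one per row; levels
#'   must be a subset of `c("healthy", "osteoarthritic")`.
#' @param patient_ids vector of patient identifiers, one per row.
#' @param unknown_patient logical; `TRUE` marks data whose true patient
#'   provenance is missing, in which case the experiment runner substitutes
#'   seeded pseudo-patients (see [assign_pseudo_patients()]).
#'
#' @return An object of class `labeled_feature_set`: a list with elements
#'   `features`, `labels` (factor with levels healthy/osteoarthritic),
#'   `patient_ids` (character) and `unknown_patient`.
#' @seealso [generate_feature_dataset()], [load_s1_dataset()]
#' @export
labeled_feature_set <- function(features, labels, patient_ids,
                                unknown_patient = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop("'features' must have at least one row and one column")
  }
  if (anyNA(features) || !all(is.finite(features))) {
    stop("'features' must be finite with no missing values")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("healthy", "osteoarthritic"))) {
    stop("labels must be 'healthy' or 'osteoarthritic'")
  }
  labels <- factor(labels, levels = c("healthy", "osteoarthritic"))
  patient_ids <- as.character(patient_ids)
  if (length(labels) != nrow(features) ||
      length(patient_ids) != nrow(features)) {
    stop("'features', 'labels' and 'patient_ids' must have matching lengths")
  }
  if (anyNA(patient_ids)) stop("missing patient identifiers")
  structure(
    list(features = features, labels = labels, patient_ids = patient_ids,
         unknown_patient = isTRUE(unknown_patient)),
    class = "labeled_feature_set"
  )
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  cat(sprintf("Labeled feature set: %d rows x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  healthy: %d, osteoarthritic: %d\n",
              sum(x$labels == "healthy"), sum(x$labels == "osteoarthritic")))
  cat(sprintf("  patients: %d%s\n", length(unique(x$patient_ids)),
              if (x$unknown_patient) " (pseudo / unknown provenance)" else ""))
  invisible(x)
}

#' @export
dim.labeled_feature_set <- function(x) dim(x$features)

# Row subset preserving class and metadata.
subset_rows <- function(data, idx) {
  labeled_feature_set(
    data$features[idx, , drop = FALSE],
    as.character(data$labels[idx]),
    data$patient_ids[idx],
    unknown_patient = data$unknown_patient
  )
}

#' Export / import a labeled feature set as CSV
#'
#' Plain-text interchange for feature sets. Numeric values are written with
#' 17 significant digits so that a write/read cycle reproduces the matrix
#' exactly.
#'
#' @param data a [labeled_feature_set()].
#' @param path file path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   returns a [labeled_feature_set()].
#' @export
write_feature_csv <- function(data, path) {
  stopifnot(inherits(data, "labeled_feature_set"))
  mat <- apply(data$features, 2, function(col) formatC(col, format = "g", digits = 17))
  mat <- matrix(mat, nrow = nrow(data$features))
  colnames(mat) <- colnames(data$features) %||%
    paste0("f", seq_len(ncol(data$features)))
  df <- data.frame(label = as.character(data$labels),
                   patient_id = data$patient_ids, mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", "patient_id")
  if (!all(need %in% names(df))) {
    stop("feature CSV must carry 'label' and 'patient_id' columns")
  }
  feat <- as.matrix(df[setdiff(names(df), need)])
  storage.mode(feat) <- "double"
  labeled_feature_set(feat, df$label, df$patient_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
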