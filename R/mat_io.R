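# Minimal MAT v5 container I/O (little-endian), sufficient for feature
# matrices and label vectors: numeric array and character array elements,
# the small-data-element format, and zlib-compressed elements. Cell and
# struct arrays are skipped with a warning.

MI_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
              `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L, `16` = 1L)

pad8 <- function(n) ((n + 7L) %/% 8L) * 8L

#' Read a MAT v5 container
#'
#' Parses numeric and character array variables from a MATLAB level-5 file
#' (the format written by MATLAB's `save -v5` and scipy's `savemat`).
#' Compressed elements are inflated with [memDecompress()].
#'
#' @param path file path.
#' @return Named list of variables: numeric arrays keep their MATLAB shape
#'   (column-major); character arrays become character vectors.
#' @seealso [write_mat5()], [load_s1_dataset()]
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 container (truncated header): ", path)
  endian_tag <- rawToChar(raw[127:128])
  if (!endian_tag %in% c("IM", "MI")) {
    stop("not a MAT v5 container (bad endian indicator): ", path)
  }
  endian <- if (endian_tag == "IM") "little" else "big"
  vars <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- mat5_read_element(raw, pos, endian)
    pos <- el$next_pos
    if (!is.null(el$value) && nzchar(el$name)) vars[[el$name]] <- el$value
  }
  vars
}

# Read one top-level or sub- element starting at pos; returns
# list(name, value, next_pos).
mat5_read_element <- function(raw, pos, endian) {
  type <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = endian)
  small_nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16L)
  if (small_nbytes != 0L) {  # small data element: data packed in bytes 5..8
    type <- bitwAnd(type, 65535L)
    nbytes <- bitwAnd(small_nbytes, 65535L)
    data <- raw[(pos + 4L):(pos + 3L + nbytes)]
    next_pos <- pos + 8L
  } else {
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                      endian = endian)
    data <- if (nbytes > 0L) raw[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    next_pos <- pos + 8L + if (type == 15L) nbytes else pad8(nbytes)
  }
  if (type == 15L) {  # miCOMPRESSED: recurse into the inflated payload
    inner <- memDecompress(data, type = "gzip")
    el <- mat5_read_element(inner, 1L, endian)
    el$next_pos <- next_pos
    return(el)
  }
  if (type == 14L) {  # miMATRIX
    el <- mat5_parse_matrix(data, endian)
    el$next_pos <- next_pos
    return(el)
  }
  list(name = "", value = mat5_decode_numeric(type, data, endian),
       type = type, next_pos = next_pos)
}

mat5_parse_matrix <- function(data, endian) {
  if (length(data) == 0L) return(list(name = "", value = NULL))
  p <- 1L
  sub <- list()
  while (p + 7L <= length(data)) {
    el <- mat5_read_element(data, p, endian)
    p <- el$next_pos
    sub[[length(sub) + 1L]] <- el
  }
  flags <- sub[[1L]]$value
  class_id <- bitwAnd(as.integer(flags[1L]), 255L)
  dims <- as.integer(sub[[2L]]$value)
  name <- rawToChar(as.raw(as.integer(sub[[3L]]$value)))
  if (class_id %in% c(1L, 2L)) {  # cell / struct: unsupported
    warning("skipping unsupported MAT variable '", name, "'")
    return(list(name = "", value = NULL))
  }
  if (length(sub) < 4L) return(list(name = name, value = NULL))
  vals <- sub[[4L]]$value
  if (class_id == 4L) {  # char array: rows are strings, column-major codes
    codes <- matrix(as.integer(vals), nrow = dims[1L])
    strings <- apply(codes, 1L, function(cw) {
      cw <- cw[cw > 0L]
      if (length(cw)) intToUtf8(cw) else ""
    })
    return(list(name = name, value = trimws(strings)))
  }
  vals <- as.double(vals)
  if (length(vals) != prod(dims)) {
    stop("MAT variable '", name, "': data length ", length(vals),
         " does not match its declared dimensions ", paste(dims, collapse = "x"))
  }
  value <- array(vals, dim = dims)
  if (length(dims) == 2L && min(dims) == 1L) value <- as.vector(value)
  list(name = name, value = value)
}

mat5_decode_numeric <- function(type, data, endian) {
  type <- as.character(type)
  if (!type %in% names(MI_SIZES)) stop("unsupported MAT data type code ", type)
  size <- MI_SIZES[[type]]
  n <- length(data) %/% size
  switch(type,
    `1` = as.integer(readBin(data, "integer", n = n, size = 1L, signed = TRUE)),
    `2` = as.integer(readBin(data, "integer", n = n, size = 1L, signed = FALSE)),
    `3` = readBin(data, "integer", n = n, size = 2L, signed = TRUE, endian = endian),
    `4` = readBin(data, "integer", n = n, size = 2L, signed = FALSE, endian = endian),
    `5` = readBin(data, "integer", n = n, size = 4L, endian = endian),
    `6` = mat5_read_uint32(data, n, endian),
    `7` = readBin(data, "double", n = n, size = 4L, endian = endian),
    `9` = readBin(data, "double", n = n, size = 8L, endian = endian),
    `12` = mat5_read_int64(data, n, endian),
    `13` = mat5_read_int64(data, n, endian),
    `16` = utf8ToInt(rawToChar(data))
  )
}

mat5_read_uint32 <- function(data, n, endian) {
  v <- readBin(data, "integer", n = n, size = 4L, endian = endian)
  out <- as.double(v)
  out[v < 0] <- out[v < 0] + 2^32
  out
}

mat5_read_int64 <- function(data, n, endian) {
  u <- mat5_read_uint32(data, 2L * n, endian)
  if (endian == "little") { lo <- u[c(TRUE, FALSE)]; hi <- u[c(FALSE, TRUE)] }
  else { hi <- u[c(TRUE, FALSE)]; lo <- u[c(FALSE, TRUE)] }
  hi_signed <- ifelse(hi >= 2^31, hi - 2^32, hi)
  hi_signed * 2^32 + lo
}

#' Write numeric variables to a MAT v5 container
#'
#' Writes double-precision arrays as uncompressed MAT level-5 elements
#' (little-endian). Used for fixture construction and for exporting feature
#' sets to MATLAB-compatible tools; a write/read cycle reproduces values
#' bit-exactly.
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by simcadx on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  header <- charToRaw(formatC(desc, width = -116))
  header <- c(header, rep(as.raw(0x20), 116L - length(header)))[1:116]
  writeBin(header, con)
  writeBin(rep(as.raw(0L), 8L), con)                       # subsystem offset
  writeBin(c(as.raw(0x00), as.raw(0x01)), con)             # version 0x0100
  writeBin(charToRaw("IM"), con)                           # endian indicator
  for (nm in names(vars)) {
    writeBin(mat5_encode_matrix(nm, vars[[nm]]), con)
  }
  invisible(path)
}

mat5_sub <- function(type, payload_raw) {
  n <- length(payload_raw)
  tag <- c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
           writeBin(as.integer(n), raw(), size = 4L, endian = "little"))
  pad <- raw(pad8(n) - n)
  c(tag, payload_raw, pad)
}

mat5_encode_matrix <- function(name, value) {
  value <- as.array(value)
  dims <- dim(value) %||% length(value)
  if (length(dims) == 1L) dims <- c(dims, 1L)
  storage.mode(value) <- "double"
  flags <- writeBin(c(6L, 0L), raw(), size = 4L, endian = "little")  # mxDOUBLE
  body <- c(
    mat5_sub(6L, flags),
    mat5_sub(5L, writeBin(as.integer(dims), raw(), size = 4L, endian = "little")),
    mat5_sub(1L, charToRaw(name)),
    mat5_sub(9L, writeBin(as.vector(value), raw(), size = 8L, endian = "little"))
  )
  tag <- c(writeBin(14L, raw(), size = 4L, endian = "little"),
           writeBin(length(body), raw(), size = 4L, endian = "little"))
  c(tag, body)
}

#' Load a deposited SIM feature dataset from a MAT v5 container
#'
#' Reads a MAT container holding high-dimensional SIM-derived geometrical
#' feature vectors with class labels (the layout of the study's deposited
#' supplementary dataset). Because the variable names inside such containers
#' are not standardized, the largest 2-D numeric array is taken as the
#' feature matrix and a numeric (or two-valued) vector of matching length as
#' the label vector; both can be overridden by name.
#'
#' Label coding: with two distinct numeric label values, the **larger** value
#' is mapped to `osteoarthritic` (covers the common 0/1 and 1/2 codings);
#' override with `positive_value`. If no patient identifier variable is
#' found, the result is flagged `unknown_patient` and the experiment runner
#' substitutes seeded pseudo-patients.
#'
#' @param path MAT v5 file path.
#' @param features_var,labels_var,patients_var optional explicit variable
#'   names inside the container.
#' @param positive_value optional label value to map to `osteoarthritic`.
#' @return A [labeled_feature_set()]; `unknown_patient` is `TRUE` when no
#'   patient variable was found.
#' @export
load_s1_dataset <- function(path, features_var = NULL, labels_var = NULL,
                            patients_var = NULL, positive_value = NULL) {
  vars <- read_mat5(path)
  if (length(vars) == 0L) stop("no readable variables in ", path)
  num <- Filter(is.numeric, vars)

  if (is.null(features_var)) {
    mats <- Filter(function(v) length(dim(v)) == 2L && min(dim(v)) > 1L, num)
    if (length(mats) == 0L) stop("no 2-D numeric feature matrix found in ", path)
    features_var <- names(mats)[which.max(vapply(mats, length, 0))]
  }
  feat <- vars[[features_var]]
  if (is.null(feat) || !is.numeric(feat)) {
    stop("feature variable '", features_var, "' missing or non-numeric")
  }
  feat <- as.matrix(feat)

  if (is.null(labels_var)) {
    cand <- names(num)[vapply(num, function(v) {
      is.null(dim(v)) || min(dim(v)) == 1L
    }, TRUE)]
    cand <- setdiff(cand, features_var)
    hit <- cand[vapply(cand, function(nm) {
      length(vars[[nm]]) %in% dim(feat) && length(unique(vars[[nm]])) == 2L
    }, TRUE)]
    if (length(hit) == 0L) {
      # fall back: any vector matching a feature dimension
      hit <- cand[vapply(cand, function(nm) length(vars[[nm]]) %in% dim(feat), TRUE)]
    }
    if (length(hit) == 0L) {
      bad <- if (length(cand)) cand[[1L]] else "<none>"
      stop("no label vector matching the feature matrix found (candidate '",
           bad, "' has incompatible length)")
    }
    labels_var <- hit[[1L]]
  }
  lab_raw <- as.vector(vars[[labels_var]])
  if (is.null(lab_raw)) stop("label variable '", labels_var, "' missing")

  # orient features so rows correspond to labels
  if (nrow(feat) != length(lab_raw)) {
    if (ncol(feat) == length(lab_raw)) feat <- t(feat)
    else stop("label variable '", labels_var, "' has length ", length(lab_raw),
              " but feature matrix '", features_var, "' has ", nrow(feat), " rows")
  }

  uv <- sort(unique(lab_raw))
  if (length(uv) != 2L) {
    stop("label variable '", labels_var, "' must take exactly 2 distinct values")
  }
  pos <- positive_value %||% uv[2L]
  labels <- ifelse(lab_raw == pos, "osteoarthritic", "healthy")

  unknown_patient <- TRUE
  pids <- rep("unknown", length(labels))
  if (!is.null(patients_var)) {
    pv <- vars[[patients_var]]
    if (is.null(pv)) stop("patient variable '", patients_var, "' missing")
    pids <- as.character(as.vector(pv))
    unknown_patient <- FALSE
  } else {
    guess <- grep("patient|subject|specimen|donor", names(vars),
                  ignore.case = TRUE, value = TRUE)
    for (nm in guess) {
      pv <- as.vector(vars[[nm]])
      if (length(pv) == length(labels)) {
        pids <- as.character(pv); unknown_patient <- FALSE; break
      }
    }
  }
  if (length(pids) != length(labels)) {
    stop("patient variable length does not match the feature rows")
  }
  labeled_feature_set(feat, labels, pids, unknown_patient = unknown_patient)
}
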