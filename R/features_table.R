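# Assembly of the full 464-feature vector and the n x 464 feature table.

feature_set_sizes <- c(STAT = 22L, COUNT = 10L, GRAD = 24L, HAAR = 96L,
                       GLCM = 312L)

#' Extract the full 464-feature vector of one ROI pair
#'
#' Concatenates the five sets in fixed order STAT (22), COUNT (10), GRAD
#' (24), HAAR (96), GLCM (312). Deterministic: the same pair always yields
#' the identical vector.
#'
#' @param pair a [roi_pair()].
#' @param spec a [glcm_spec()] for the co-occurrence set.
#' @return named numeric vector of length 464 with a `set_of` attribute
#'   assigning each feature to its set.
#' @export
extract_all <- function(pair, spec = glcm_spec()) {
  vals <- tryCatch({
    stat <- c(stat_features(pair$le, "LE", pair$bit_depth),
              stat_features(pair$rc, "RC", pair$bit_depth))
    cnt <- c(count_features(pair$le, "LE"), count_features(pair$rc, "RC"))
    c(stat, cnt, grad_features(pair), haar_stat_features(pair),
      glcm_features(pair, spec))
  }, error = function(e) {
    stop(sprintf("feature extraction failed for lesion '%s': %s",
                 pair$lesion_id, conditionMessage(e)), call. = FALSE)
  })
  stopifnot(length(vals) == 464L)
  attr(vals, "set_of") <- rep(names(feature_set_sizes), feature_set_sizes)
  vals
}

#' Names and provenance of the 464 features
#'
#' @param spec a [glcm_spec()] (affects nothing but kept for symmetry).
#' @return data frame with columns `feature`, `set`, `source` (LE/RC),
#'   `transform` (none, Gmag/Gdir, Haar band, band + direction) and
#'   `statistic`.
#' @export
feature_dictionary <- function(spec = glcm_spec()) {
  ref <- extract_all(
    roi_pair("dict", matrix(rep(0:7, 8), 8, 8), matrix(rep(0:7, 8), 8, 8)),
    spec)
  nm <- names(ref)
  parts <- strsplit(nm, "_")
  data.frame(
    feature = nm,
    set = attr(ref, "set_of"),
    source = vapply(parts, `[`, "", 1L),
    statistic = vapply(parts, `[`, "", 2L),
    transform = vapply(parts, function(p) {
      if (length(p) <= 2L) "none" else paste(p[-(1:2)], collapse = "_")
    }, ""),
    stringsAsFactors = FALSE)
}

#' Extract the feature table of a dataset
#'
#' @param pairs list of [roi_pair()].
#' @param labels binary labels aligned with `pairs` (0 benign, 1 malignant).
#' @param spec a [glcm_spec()].
#' @param verbose print progress every 10 lesions.
#' @return a `cesm_features` data frame: `lesion_id`, `label`, then 464
#'   feature columns, with the set assignment in attribute `set_of`.
#' @export
extract_features <- function(pairs, labels, spec = glcm_spec(),
                             verbose = FALSE) {
  stopifnot(length(pairs) == length(labels), all(labels %in% 0:1))
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    rows[[i]] <- extract_all(pairs[[i]], spec)
    if (verbose && i %% 10L == 0L) {
      message(sprintf("extracted %d/%d lesions", i, length(pairs)))
    }
  }
  mat <- do.call(rbind, rows)
  df <- data.frame(lesion_id = vapply(pairs, `[[`, "", "lesion_id"),
                   label = as.integer(labels), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "set_of") <- attr(rows[[1]], "set_of")
  class(df) <- c("cesm_features", "data.frame")
  df
}

#' @export
print.cesm_features <- function(x, ...) {
  cat(sprintf("<cesm_features> %d ROIs x %d features (%d benign, %d malignant)\n",
              nrow(x), ncol(x) - 2L, sum(x$label == 0), sum(x$label == 1)))
  invisible(x)
}

#' Extract one feature set's columns as a plain matrix
#'
#' @param features a `cesm_features` table.
#' @param set one of `"STAT", "COUNT", "GRAD", "HAAR", "GLCM"`.
#' @return numeric matrix (rows = ROIs) of that set's features.
#' @export
feature_set_matrix <- function(features, set) {
  set_of <- attr(features, "set_of")
  stopifnot(!is.null(set_of), set %in% names(feature_set_sizes))
  as.matrix(features[, c(FALSE, FALSE, set_of == set), drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' @param features a `cesm_features` table.
#' @param path CSV path.
#' @return `path` (write) or the re-read `cesm_features` (read).
#' @export
write_features <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) == 466L,
            identical(names(df)[1:2], c("lesion_id", "label")))
  attr(df, "set_of") <- rep(names(feature_set_sizes), feature_set_sizes)
  class(df) <- c("cesm_features", "data.frame")
  df
}
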