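# Lesion manifests and ROI image-pair loading.

#' Construct a validated LE/RC ROI pair
#'
#' Bundles the low-energy (LE) and recombined (RC) regions of interest of one
#' lesion. The two crops are drawn independently on each view, so their
#' dimensions may differ; every feature is computed per image, never
#' pixelwise across the pair.
#'
#' @param lesion_id character scalar identifying the lesion.
#' @param le,rc integer-valued matrices of gray levels (rows x columns).
#' @param bit_depth stored bit depth, 8 or 16; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `roi_pair`.
#' @details A minimum side of 8 pixels is enforced: two Haar decomposition
#'   levels halve each dimension twice, and the second-level sub-bands must
#'   still admit a distance-2 co-occurrence offset upstream of nothing
#'   smaller than a 2x2 band.
#' @export
#' @examples
#' p <- roi_pair("demo", matrix(0:63, 8, 8), matrix(63:0, 8, 8))
roi_pair <- function(lesion_id, le, rc, bit_depth = 8L) {
  stopifnot(is.character(lesion_id), length(lesion_id) == 1L)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16", call. = FALSE)
  }
  check_roi_image <- function(x, which) {
    if (!is.matrix(x) || !is.numeric(x)) {
      stop(sprintf("%s image of '%s' must be a single-channel numeric matrix",
                   which, lesion_id), call. = FALSE)
    }
    if (nrow(x) < 8L || ncol(x) < 8L) {
      stop(sprintf("%s image of '%s' is %dx%d; ROI sides must be >= 8 pixels",
                   which, lesion_id, nrow(x), ncol(x)), call. = FALSE)
    }
    if (anyNA(x) || any(x < 0) || any(x > 2^bit_depth - 1)) {
      stop(sprintf("%s image of '%s' has intensities outside [0, %d]",
                   which, lesion_id, 2^bit_depth - 1), call. = FALSE)
    }
    if (any(x != round(x))) {
      stop(sprintf("%s image of '%s' must hold integer gray levels",
                   which, lesion_id), call. = FALSE)
    }
    storage.mode(x) <- "double"
    x
  }
  structure(list(lesion_id = lesion_id,
                 le = check_roi_image(le, "LE"),
                 rc = check_roi_image(rc, "RC"),
                 bit_depth = as.integer(bit_depth)),
            class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("<roi_pair> lesion '%s': LE %dx%d, RC %dx%d, %d-bit\n",
              x$lesion_id, nrow(x$le), ncol(x$le),
              nrow(x$rc), ncol(x$rc), x$bit_depth))
  invisible(x)
}

manifest_columns <- c("lesion_id", "patient_id", "birads", "le_path", "rc_path")

#' Map a BIRADS class to the binary histology-proxy label
#'
#' BIRADS 2 and 3 lesions are treated as benign (0), BIRADS 4 and 5 as
#' malignant (1).
#'
#' @param birads integer vector with values in {2,3,4,5}.
#' @return integer vector of 0/1 labels.
#' @export
birads_to_label <- function(birads) {
  bad <- which(!birads %in% 2:5)
  if (length(bad)) {
    stop(sprintf("BIRADS class outside {2,3,4,5} in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  as.integer(birads >= 4)
}

#' Read a lesion manifest
#'
#' The manifest is a CSV with columns `lesion_id`, `patient_id`, `birads`,
#' `le_path`, `rc_path` (extra columns are kept but ignored, with a warning).
#' Each row is one ROI; a patient may own several ROIs. The binary label is
#' derived from the BIRADS class via [birads_to_label()].
#'
#' @param path path to the manifest CSV.
#' @return A `cesm_manifest` data frame with a derived `label` column and a
#'   `counts` attribute `c(n_benign, n_malignant)`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(manifest_columns, "label"))
  if (length(extra)) {
    warning("ignoring extra manifest column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  as_manifest(df[manifest_columns])
}

## Validate a manifest data frame and attach label + counts.
as_manifest <- function(df) {
  if (nrow(df) == 0L) stop("manifest has no records", call. = FALSE)
  if (anyDuplicated(df$lesion_id)) {
    stop("duplicate lesion_id in manifest", call. = FALSE)
  }
  df$lesion_id <- as.character(df$lesion_id)
  df$patient_id <- as.character(df$patient_id)
  df$label <- birads_to_label(df$birads)
  attr(df, "counts") <- c(n_benign = sum(df$label == 0L),
                          n_malignant = sum(df$label == 1L))
  class(df) <- c("cesm_manifest", "data.frame")
  df
}

#' Write a lesion manifest
#'
#' @param manifest a `cesm_manifest` (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest[c(manifest_columns, "label")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @export
print.cesm_manifest <- function(x, ...) {
  n <- attr(x, "counts")
  cat(sprintf("<cesm_manifest> %d ROIs from %d patients (%d benign, %d malignant)\n",
              nrow(x), length(unique(x$patient_id)),
              n["n_benign"], n["n_malignant"]))
  print(as.data.frame(head(x, 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

## Read one single-channel raster (PNG or TIFF) as an integer gray-level
## matrix, returning list(pixels, bit_depth). Multi-channel images are
## rejected; 16-bit depth is preserved.
read_gray_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) {
      stop("multi-channel image supplied, single-channel ROI required: ",
           path, call. = FALSE)
    }
    img <- img[, , 1]
  }
  bits <- if (bits > 8) 16L else 8L
  list(pixels = round(img * (2^bits - 1)), bit_depth = bits)
}

#' Load and validate the LE/RC image pair of one lesion record
#'
#' @param record one row of a [read_manifest()] result (or any list with
#'   `lesion_id`, `le_path`, `rc_path`).
#' @return a validated [roi_pair()].
#' @export
load_roi_pair <- function(record) {
  le <- read_gray_raster(record$le_path)
  rc <- read_gray_raster(record$rc_path)
  bits <- max(le$bit_depth, rc$bit_depth)
  rescale <- function(r) {
    if (r$bit_depth == bits) r$pixels
    else round(r$pixels / (2^r$bit_depth - 1) * (2^bits - 1))
  }
  roi_pair(as.character(record$lesion_id), rescale(le), rescale(rc),
           bit_depth = bits)
}

#' Load every ROI pair referenced by a manifest
#'
#' @param manifest a `cesm_manifest`.
#' @param base_dir optional directory that relative image paths are resolved
#'   against.
#' @return list of [roi_pair()] objects in manifest order.
#' @export
load_dataset <- function(manifest, base_dir = NULL) {
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    if (!is.null(base_dir)) {
      rec$le_path <- file.path(base_dir, rec$le_path)
      rec$rc_path <- file.path(base_dir, rec$rc_path)
    }
    tryCatch(load_roi_pair(rec),
             error = function(e) {
               stop(sprintf("lesion '%s': %s", rec$lesion_id,
                            conditionMessage(e)), call. = FALSE)
             })
  })
}
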