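# Correlation-matrix PCA per feature set with explained-variance retention.

#' Fit a correlation-matrix PCA on one feature set
#'
#' Features are standardized (mean 0, sd 1, denominator n-1) and the
#' eigen-decomposition of their correlation matrix taken. Zero-variance
#' features are dropped with a warning before standardization. When the
#' number of features exceeds the number of rows the decomposition is
#' computed through the SVD of the standardized data, which yields the
#' identical nonzero eigenvalues and loadings. Eigenvector signs are fixed
#' so each column's largest-magnitude entry is positive. Eigenvalues sum to
#' the number of (retained) features, the trace of the correlation matrix.
#'
#' @param x numeric matrix (rows = ROIs, named columns = features), n >= 3.
#' @param set_id label for the set (e.g. `"HAAR"`); used to name components.
#' @param threshold explained-variance proportion that the retained
#'   components must exceed (default 0.8).
#' @return a `cesm_pca` object: `loadings` (m x K orthonormal columns),
#'   `eigenvalues` (length K, non-increasing), `explained` (eigenvalues/m),
#'   `retained_p`, `means`, `sds`, `features`, `dropped`.
#' @export
#' @examples
#' x <- cbind(a = rnorm(20))
#' x <- cbind(x, b = x[, "a"], c = rnorm(20))
#' fit <- fit_pca(x, "TOY")
#' fit$explained   # ~ {2/3, 1/3, 0}
fit_pca <- function(x, set_id = "SET", threshold = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 rows", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  sds_all <- apply(x, 2, sd)
  dropped <- colnames(x)[sds_all == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance feature(s) in %s",
                    length(dropped), set_id), call. = FALSE)
    x <- x[, sds_all > 0, drop = FALSE]
  }
  m <- ncol(x)
  if (m == 0L) stop("all features constant; PCA undefined", call. = FALSE)
  n <- nrow(x)
  means <- colMeans(x)
  sds <- apply(x, 2, sd)
  z <- scale(x, center = means, scale = sds)
  if (m <= n) {
    R <- crossprod(z) / (n - 1)
    eig <- eigen(R, symmetric = TRUE)
    lambda <- pmax(eig$values, 0)
    gamma <- eig$vectors
  } else {
    sv <- svd(z)
    lambda <- sv$d^2 / (n - 1)
    gamma <- sv$v
  }
  ## sign convention: largest-|loading| entry positive in every column
  for (k in seq_len(ncol(gamma))) {
    j <- which.max(abs(gamma[, k]))
    if (gamma[j, k] < 0) gamma[, k] <- -gamma[, k]
  }
  rownames(gamma) <- colnames(x)
  colnames(gamma) <- paste0(set_id, "_PC", seq_len(ncol(gamma)))
  explained <- lambda / m
  model <- structure(list(set_id = set_id, loadings = gamma,
                          eigenvalues = lambda, explained = explained,
                          means = means, sds = sds,
                          features = colnames(x), dropped = dropped,
                          n = n, m = m),
                     class = "cesm_pca")
  model$retained_p <- select_components(model, threshold)
  model
}

#' Number of components retained by the explained-variance criterion
#'
#' The smallest p for which the cumulative explained-variance proportion
#' exceeds the threshold.
#'
#' @param model a `cesm_pca` fit.
#' @param threshold proportion in (0, 1), default 0.8.
#' @return integer p.
#' @export
select_components <- function(model, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  cum <- cumsum(model$explained)
  p <- which(cum > threshold)
  if (length(p) == 0L) length(cum) else min(p)
}

#' Project a feature table onto retained principal components
#'
#' Standardizes `newdata` with the *stored* training means and sds (never
#' re-estimated, so no test-fold leakage) and projects onto the first
#' `n_components` loadings.
#'
#' @param object a `cesm_pca` fit.
#' @param newdata matrix or data frame containing the model's feature
#'   columns.
#' @param n_components how many leading components to return (default
#'   `retained_p`).
#' @param ... unused.
#' @return n x p score matrix with columns labelled `SET_PCk`.
#' @export
predict.cesm_pca <- function(object, newdata, n_components = NULL, ...) {
  p <- n_components %||% object$retained_p
  p <- min(p, ncol(object$loadings))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks feature column(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  z <- scale(x, center = object$means, scale = object$sds)
  z %*% object$loadings[, seq_len(p), drop = FALSE]
}

#' Features contributing most to one principal component
#'
#' Ranks features by loading magnitude on component `k`, reporting at most
#' `max_report` whose magnitude is at least `floor` times the component's
#' largest magnitude (features with coefficients close to zero are
#' excluded).
#'
#' @param model a `cesm_pca` fit.
#' @param k component index.
#' @param max_report maximum number of features reported (default 5).
#' @param floor fraction of the maximum magnitude below which features are
#'   dropped (default 0.25).
#' @return data frame with `feature`, `loading`, `sign`, ranked by
#'   magnitude.
#' @export
important_loadings <- function(model, k, max_report = 5L, floor = 0.25) {
  if (k < 1L || k > ncol(model$loadings)) {
    stop("component index out of bounds", call. = FALSE)
  }
  l <- model$loadings[, k]
  ord <- order(abs(l), decreasing = TRUE)
  keep <- ord[abs(l[ord]) >= floor * max(abs(l))]
  keep <- keep[seq_len(min(max_report, length(keep)))]
  data.frame(feature = model$features[keep],
             loading = unname(l[keep]),
             sign = ifelse(l[keep] >= 0, "+", "-"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cesm_pca <- function(x, ...) {
  cat(sprintf("<cesm_pca> set %s: %d features, %d rows; %d PCs retained (>%.0f%% variance)\n",
              x$set_id, x$m, x$n, x$retained_p,
              100 * cumsum(x$explained)[x$retained_p]))
  if (length(x$dropped)) {
    cat("  dropped constant features:", length(x$dropped), "\n")
  }
  ev <- head(x$explained, 8)
  cat("  explained:", paste(sprintf("%.3f", ev), collapse = " "),
      if (length(x$explained) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
summary.cesm_pca <- function(object, max_report = 5L, floor = 0.25, ...) {
  reports <- lapply(seq_len(object$retained_p), function(k) {
    r <- important_loadings(object, k, max_report, floor)
    cbind(set = object$set_id, pc = k, rank = seq_len(nrow(r)), r)
  })
  out <- do.call(rbind, reports)
  class(out) <- c("summary.cesm_pca", "data.frame")
  out
}

#' Serialize / load a PCA model as JSON
#'
#' @param model a `cesm_pca` fit.
#' @param path JSON path.
#' @return `path` (write); a `cesm_pca` (read).
#' @export
write_pca <- function(model, path) {
  obj <- unclass(model)
  obj$loadings <- as.data.frame(obj$loadings)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- as.matrix(obj$loadings)
  rownames(obj$loadings) <- obj$features
  obj$means <- unlist(obj$means)
  obj$sds <- unlist(obj$sds)
  names(obj$means) <- names(obj$sds) <- obj$features
  structure(obj, class = "cesm_pca")
}
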