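# Repeated stratified k-fold cross-validation with Youden-thresholded
# metrics.

#' Cross-validation configuration
#'
#' @param n_rounds number of repeated rounds (default 100).
#' @param n_folds folds per round (default 10).
#' @param stratified stratify folds by class (default TRUE); with 15 benign
#'   among 58 ROIs unstratified folds are frequently single-class, so
#'   stratification is the default. Requires each class to have at least
#'   `n_folds` members.
#' @param base_seed integer; round r uses fold seed `base_seed + r` and each
#'   fold fit derives its own classifier seed, so a full evaluation is a
#'   pure function of (data, config, base_seed).
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_rounds = 100L, n_folds = 10L, stratified = TRUE,
                      base_seed = 1L) {
  stopifnot(n_rounds >= 1L, n_folds >= 2L)
  structure(list(n_rounds = as.integer(n_rounds), n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified),
                 base_seed = as.integer(base_seed)),
            class = "cv_config")
}

## Stratified (or plain) fold assignment for one round.
make_folds <- function(labels, cv, round) {
  n <- length(labels)
  set.seed(derive_seed(cv$base_seed, round))
  folds <- integer(n)
  if (cv$stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[sample(idx)] <- rep_len(seq_len(cv$n_folds), length(idx))
    }
  } else {
    folds[sample(n)] <- rep_len(seq_len(cv$n_folds), n)
  }
  folds
}

## --- fold design abstraction -------------------------------------------
## cross_validate() and forward_select() see candidate variables through
## fold_design(data, cols, train, test): a plain score matrix subsets
## columns (PCA fitted once, globally); a pc_candidates object refits the
## per-set PCA on the training rows of every fold (leakage-free mode).

fold_design <- function(data, cols, train, test, round = 0L, fold = 0L) {
  UseMethod("fold_design")
}

#' @export
fold_design.matrix <- function(data, cols, train, test, round = 0L,
                               fold = 0L) {
  list(train = data[train, cols, drop = FALSE],
       test = data[test, cols, drop = FALSE])
}

#' Labels of the candidate variables in a pool
#'
#' @param data a candidate pool: a score matrix or a [pc_candidates()].
#' @return character vector of candidate labels (`SET_PCk`).
#' @export
candidate_labels <- function(data) UseMethod("candidate_labels")

#' @export
candidate_labels.matrix <- function(data) colnames(data)

#' Per-fold PCA candidate pool
#'
#' Wraps the raw per-set feature matrices so that cross-validation refits
#' each set's PCA on the training rows of every fold and projects the held
#' out rows with the training standardization — no test-fold leakage. The
#' candidate labels (`SET_PCk`) are fixed by a reference fit on all rows;
#' per-fold fits are cached per (set, round, fold).
#'
#' @param feature_sets named list of numeric matrices (one per set, rows
#'   aligned).
#' @param pcs named list giving, per set, which component indices are
#'   candidates (default: the reference fit's retained components).
#' @param threshold explained-variance threshold for the reference fits.
#' @return a `pc_candidates` object usable wherever a score matrix is.
#' @export
pc_candidates <- function(feature_sets, pcs = NULL, threshold = 0.8) {
  ref <- lapply(names(feature_sets), function(s) {
    suppressWarnings(fit_pca(feature_sets[[s]], s, threshold))
  })
  names(ref) <- names(feature_sets)
  if (is.null(pcs)) {
    pcs <- lapply(ref, function(f) seq_len(f$retained_p))
  }
  labels <- unlist(lapply(names(feature_sets), function(s) {
    paste0(s, "_PC", pcs[[s]])
  }))
  structure(list(feature_sets = feature_sets, pcs = pcs, ref = ref,
                 threshold = threshold, labels = labels,
                 cache = new.env(parent = emptyenv())),
            class = "pc_candidates")
}

#' @export
candidate_labels.pc_candidates <- function(data) data$labels

#' @export
fold_design.pc_candidates <- function(data, cols, train, test, round = 0L,
                                      fold = 0L) {
  sets <- unique(sub("_PC[0-9]+$", "", cols))
  tr <- list(); te <- list()
  for (s in sets) {
    key <- sprintf("%s.%d.%d", s, round, fold)
    hit <- get0(key, envir = data$cache)
    if (is.null(hit) || !identical(hit$train, train)) {
      ## fit once per (set, round, fold) and project every candidate PC of
      ## the set, so later candidate evaluations just subset columns
      fit <- suppressWarnings(
        fit_pca(data$feature_sets[[s]][train, , drop = FALSE], s,
                data$threshold))
      kall <- min(max(data$pcs[[s]]), ncol(fit$loadings))
      hit <- list(
        train = train,
        sc_tr = predict(fit, data$feature_sets[[s]][train, , drop = FALSE],
                        n_components = kall),
        sc_te = predict(fit,
                        data$feature_sets[[s]][-train, , drop = FALSE],
                        n_components = kall),
        test_rows = setdiff(seq_len(nrow(data$feature_sets[[s]])), train))
      assign(key, hit, envir = data$cache)
    }
    want <- cols[startsWith(cols, paste0(s, "_PC"))]
    k <- pmin(as.integer(sub(".*_PC", "", want)), ncol(hit$sc_tr))
    tr[[s]] <- hit$sc_tr[, k, drop = FALSE]
    te[[s]] <- hit$sc_te[match(test, hit$test_rows), k, drop = FALSE]
    colnames(tr[[s]]) <- colnames(te[[s]]) <- want
  }
  list(train = do.call(cbind, tr)[, cols, drop = FALSE],
       test = do.call(cbind, te)[, cols, drop = FALSE])
}

#' Repeated stratified cross-validation of one candidate model
#'
#' Per round: a seeded stratified fold assignment; per fold: the classifier
#' is fitted on the training folds and scores the held-out fold; the
#' round's pooled out-of-fold scores give that round's AUC and
#' Youden-thresholded accuracy/sensitivity/specificity. The summary reports
#' medians (and the AUC IQR) across rounds, as percentages.
#'
#' @param data candidate variables: a score matrix with labelled columns, or
#'   a [pc_candidates()] pool for per-fold PCA refits.
#' @param labels binary labels (1 = malignant).
#' @param clf a [classifier_spec()].
#' @param cv a [cv_config()].
#' @param cols which candidate columns to use (default: all).
#' @return a `cesm_cv` object: `summary` (named vector of median
#'   percentages), `per_round` data frame, `scores` (n x n_rounds
#'   out-of-fold score matrix), `cols`.
#' @export
cross_validate <- function(data, labels, clf = classifier_spec("RF"),
                           cv = cv_config(), cols = NULL) {
  labels <- as.integer(labels)
  cols <- cols %||% candidate_labels(data)
  n <- length(labels)
  if (n < cv$n_folds) stop("fewer samples than folds", call. = FALSE)
  counts <- table(factor(labels, levels = 0:1))
  if (any(counts == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (cv$stratified && any(counts < cv$n_folds)) {
    stop(sprintf(
      "stratified %d-fold CV needs >= %d samples per class (have %d/%d)",
      cv$n_folds, cv$n_folds, counts[1], counts[2]), call. = FALSE)
  }
  if (!cv$stratified && any(counts < 2L)) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  scores <- matrix(NA_real_, n, cv$n_rounds)
  per_round <- vector("list", cv$n_rounds)
  for (r in seq_len(cv$n_rounds)) {
    folds <- make_folds(labels, cv, r)
    oof <- rep(NA_real_, n)
    for (f in seq_len(cv$n_folds)) {
      test <- which(folds == f)
      train <- which(folds != f)
      if (length(unique(labels[train])) < 2L) {
        stop("training fold with a single class; use stratified folds",
             call. = FALSE)
      }
      d <- fold_design(data, cols, train, test, round = r, fold = f)
      score_fun <- fit_classifier(clf, d$train, labels[train],
                                  seed = derive_seed(cv$base_seed * 1000 + r, f))
      oof[test] <- score_fun(d$test)
    }
    scores[, r] <- oof
    y <- suppressWarnings(youden_metrics(oof, labels))
    per_round[[r]] <- data.frame(round = r, auc = 100 * auc(oof, labels),
                                 accuracy = y$accuracy,
                                 sensitivity = y$sensitivity,
                                 specificity = y$specificity,
                                 threshold = y$threshold)
  }
  pr <- do.call(rbind, per_round)
  summ <- c(auc_median = median(pr$auc), auc_iqr = IQR(pr$auc),
            accuracy_median = median(pr$accuracy),
            sensitivity_median = median(pr$sensitivity),
            specificity_median = median(pr$specificity),
            youden_threshold_median = median(pr$threshold),
            auc_q25 = unname(quantile(pr$auc, 0.25)))
  structure(list(summary = summ, per_round = pr, scores = scores,
                 cols = cols, clf = clf$kind, cv = cv),
            class = "cesm_cv")
}

#' @export
print.cesm_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cesm_cv> %s on {%s}: %d x %d-fold CV\n", x$clf,
              paste(x$cols, collapse = ", "), x$cv$n_rounds, x$cv$n_folds))
  cat(sprintf("  median AUC %.2f%% (IQR %.2f), acc %.2f%%, sens %.2f%%, spec %.2f%%\n",
              s["auc_median"], s["auc_iqr"], s["accuracy_median"],
              s["sensitivity_median"], s["specificity_median"]))
  invisible(x)
}
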