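# Full evaluation: forward selection per feature set and on the pooled
# candidate set, for each of the three classifiers.

#' Evaluate all classifier x candidate-set combinations
#'
#' Runs forward selection for each of the five per-set principal-component
#' pools and for the pooled candidates, with each classifier: up to
#' 6 x 3 = 18 selection paths. Per-set best combinations are reported by
#' component number (`"1 + 5"`); pooled combinations carry set-qualified
#' shorthand (`"H2 + G1 + H12"`).
#'
#' @param per_set_scores named list of per-set candidate pools (score
#'   matrices or [pc_candidates()]), rows aligned with `labels`.
#' @param pooled pooled candidate pool spanning every set (score matrix or
#'   [pc_candidates()]).
#' @param labels binary labels (1 = malignant).
#' @param classifiers character vector among `"RF", "NB", "GLM"`.
#' @param cv a [cv_config()].
#' @param max_steps optional cap on each selection path length.
#' @param verbose log each path as it completes.
#' @return a `cesm_evaluation` object with `per_set` and `pooled` report
#'   data frames (columns Set, Classifier, Best combination,
#'   AUC/Acc/Sens/Spec as percentages) and all `paths`.
#' @export
evaluate_all <- function(per_set_scores, pooled, labels,
                         classifiers = c("RF", "NB", "GLM"),
                         cv = cv_config(), max_steps = NULL,
                         verbose = FALSE) {
  paths <- list()
  per_set_rows <- list()
  pooled_rows <- list()
  for (set in names(per_set_scores)) {
    for (kind in classifiers) {
      sel <- forward_select(per_set_scores[[set]], labels,
                            classifier_spec(kind), cv, max_steps = max_steps)
      paths[[paste(set, kind, sep = ".")]] <- sel
      b <- sel$best
      per_set_rows[[length(per_set_rows) + 1L]] <- data.frame(
        set = set, classifier = kind,
        best_combination = paste(sub(".*_PC", "", b$subset), collapse = " + "),
        auc = b$summary[["auc_median"]],
        accuracy = b$summary[["accuracy_median"]],
        sensitivity = b$summary[["sensitivity_median"]],
        specificity = b$summary[["specificity_median"]])
      if (verbose) message(sprintf("done: %s / %s", set, kind))
    }
  }
  for (kind in classifiers) {
    sel <- forward_select(pooled, labels, classifier_spec(kind), cv,
                          max_steps = max_steps)
    paths[[paste("POOLED", kind, sep = ".")]] <- sel
    b <- sel$best
    pooled_rows[[length(pooled_rows) + 1L]] <- data.frame(
      classifier = kind,
      best_combination = paste(pc_short_label(b$subset), collapse = " + "),
      auc = b$summary[["auc_median"]],
      accuracy = b$summary[["accuracy_median"]],
      sensitivity = b$summary[["sensitivity_median"]],
      specificity = b$summary[["specificity_median"]])
    if (verbose) message(sprintf("done: pooled / %s", kind))
  }
  structure(list(per_set = do.call(rbind, per_set_rows),
                 pooled = do.call(rbind, pooled_rows),
                 paths = paths, cv = cv),
            class = "cesm_evaluation")
}

format_report <- function(df) {
  for (col in c("auc", "accuracy", "sensitivity", "specificity")) {
    df[[col]] <- sprintf("%.2f", df[[col]])
  }
  df
}

#' @export
print.cesm_evaluation <- function(x, ...) {
  cat("<cesm_evaluation>\nPer-set best models:\n")
  print(format_report(x$per_set), row.names = FALSE)
  cat("\nPooled candidate set:\n")
  print(format_report(x$pooled), row.names = FALSE)
  invisible(x)
}

#' Write evaluation reports as CSV
#'
#' Two tables: per-set (rows = set x classifier) and pooled (rows =
#' classifier), percentages with two decimals.
#'
#' @param evaluation a `cesm_evaluation`.
#' @param dir output directory.
#' @return character vector of the written paths, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "report_per_set.csv")
  p2 <- file.path(dir, "report_pooled.csv")
  write.csv(format_report(evaluation$per_set), p1, row.names = FALSE)
  write.csv(format_report(evaluation$pooled), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
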