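# Greedy forward selection of principal components by median CV AUC.

#' Sequential forward selection of principal components
#'
#' Starting from the single candidate with the highest median AUC over the
#' repeated cross-validation, greedily adds at each step the candidate that
#' maximizes the median AUC of the grown model, until every candidate is
#' included (or `max_steps` is reached). Ties in median AUC are broken by
#' the higher 25th-percentile AUC, then by the lower candidate index. The
#' best subset is the step with maximal median AUC; ties go to the smaller
#' subset.
#'
#' @inheritParams cross_validate
#' @param max_steps optional cap on the path length (default: all
#'   candidates).
#' @param verbose print each step as it is chosen.
#' @return a `cesm_selection` object: `steps` data frame (step, added,
#'   subset, metrics), `best` (list with `subset` and `summary`),
#'   `evaluations` (list of `cesm_cv` along the path).
#' @export
forward_select <- function(data, labels, clf = classifier_spec("RF"),
                           cv = cv_config(), max_steps = NULL,
                           verbose = FALSE) {
  candidates <- candidate_labels(data)
  stopifnot(length(candidates) >= 1L)
  max_steps <- min(max_steps %||% length(candidates), length(candidates))
  remaining <- candidates
  current <- character(0)
  steps <- vector("list", max_steps)
  evals <- vector("list", max_steps)
  for (step in seq_len(max_steps)) {
    best_cand <- NULL
    for (cand in remaining) {
      res <- cross_validate(data, labels, clf, cv, cols = c(current, cand))
      med <- res$summary[["auc_median"]]
      q25 <- res$summary[["auc_q25"]]
      idx <- match(cand, candidates)
      if (is.null(best_cand) || med > best_cand$med + 1e-12 ||
          (abs(med - best_cand$med) <= 1e-12 &&
           (q25 > best_cand$q25 + 1e-12 ||
            (abs(q25 - best_cand$q25) <= 1e-12 && idx < best_cand$idx)))) {
        best_cand <- list(cand = cand, med = med, q25 = q25, idx = idx,
                          res = res)
      }
    }
    current <- c(current, best_cand$cand)
    remaining <- setdiff(remaining, best_cand$cand)
    evals[[step]] <- best_cand$res
    steps[[step]] <- data.frame(
      step = step, added = best_cand$cand,
      subset = paste(current, collapse = " + "),
      t(best_cand$res$summary))
    if (verbose) {
      message(sprintf("step %d: + %s (median AUC %.2f%%)", step,
                      best_cand$cand, best_cand$med))
    }
  }
  steps <- do.call(rbind, steps)
  best_i <- which.max(steps$auc_median)   # which.max takes the first maximum
  structure(list(steps = steps,
                 best = list(step = best_i,
                             subset = strsplit(steps$subset[best_i], " \\+ ")[[1]],
                             summary = evals[[best_i]]$summary),
                 evaluations = evals, clf = clf$kind, cv = cv),
            class = "cesm_selection")
}

## "HAAR_PC2" -> "H2", "GLCM_PC11" -> "GL11", per-set shorthand used in the
## pooled report.
set_shorthand <- c(STAT = "S", COUNT = "C", GRAD = "G", HAAR = "H",
                   GLCM = "GL")

pc_short_label <- function(labels) {
  set <- sub("_PC[0-9]+$", "", labels)
  k <- sub(".*_PC", "", labels)
  ifelse(set %in% names(set_shorthand),
         paste0(set_shorthand[set], k), labels)
}

#' @export
print.cesm_selection <- function(x, ...) {
  cat(sprintf("<cesm_selection> %s, %d steps\n", x$clf, nrow(x$steps)))
  b <- x$best
  cat(sprintf("  best: %s (median AUC %.2f%%, acc %.2f%%, sens %.2f%%, spec %.2f%%)\n",
              paste(pc_short_label(b$subset), collapse = " + "),
              b$summary["auc_median"], b$summary["accuracy_median"],
              b$summary["sensitivity_median"], b$summary["specificity_median"]))
  invisible(x)
}

#' @export
summary.cesm_selection <- function(object, ...) {
  object$steps[c("step", "added", "subset", "auc_median", "accuracy_median",
                 "sensitivity_median", "specificity_median")]
}

#' @export
plot.cesm_selection <- function(x, ...) {
  plot(x$steps$step, x$steps$auc_median, type = "b", pch = 19,
       xlab = "forward-selection step", ylab = "median AUC (%)",
       main = sprintf("Forward selection (%s)", x$clf), ...)
  abline(v = x$best$step, lty = 2)
  invisible(x)
}
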