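# The three classifiers scored under cross-validation. Each returns a
# continuous malignancy score in [0, 1] for ROC analysis: RF = fraction of
# trees voting malignant, NB = posterior probability, GLM = sigmoid output.

#' Classifier specification
#'
#' Hyperparameters are frozen before any cross-validation and identical for
#' every candidate subset: random forest with 100 trees, Gini split
#' criterion and `floor(sqrt(p))` variables per split; Gaussian naive Bayes
#' with per-class variance floors of 1e-9; logistic regression, unpenalized
#' where the design is full rank with a tiny ridge (1e-6) fallback for
#' degenerate designs.
#'
#' @param kind `"RF"`, `"NB"` or `"GLM"`.
#' @param ntree random-forest tree count.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("RF", "NB", "GLM"), ntree = 100L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, ntree = as.integer(ntree)), class = "classifier_spec")
}

## Fit on a training design and return a scoring closure for new rows.
fit_classifier <- function(spec, x, y, seed = NULL) {
  x <- as.matrix(x)
  switch(spec$kind,
    RF = {
      if (!is.null(seed)) set.seed(seed)
      fit <- randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = spec$ntree,
        mtry = max(1L, floor(sqrt(ncol(x)))))
      function(newx) {
        unname(stats::predict(fit, as.matrix(newx), type = "prob")[, "1"])
      }
    },
    NB = {
      fit <- fit_gaussian_nb(x, y)
      function(newx) predict_gaussian_nb(fit, as.matrix(newx))
    },
    GLM = {
      beta <- fit_logistic(x, y)
      function(newx) {
        as.vector(plogis(cbind(1, as.matrix(newx)) %*% beta))
      }
    })
}

## Gaussian naive Bayes with a per-class variance floor so constant
## predictors in tiny folds stay finite.
fit_gaussian_nb <- function(x, y, var_floor = 1e-9) {
  classes <- c(0, 1)
  stats_by <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xc),
         var = pmax(apply(xc, 2, var), var_floor),
         prior = nrow(xc) / nrow(x))
  })
  names(stats_by) <- classes
  stats_by
}

predict_gaussian_nb <- function(fit, newx) {
  loglik <- function(cl) {
    m <- fit[[cl]]$mean; v <- fit[[cl]]$var
    lp <- -0.5 * (sweep(newx, 2, m)^2 %*% (1 / v)) -
      0.5 * sum(log(2 * pi * v)) + log(fit[[cl]]$prior)
    as.vector(lp)
  }
  l0 <- loglik("0"); l1 <- loglik("1")
  1 / (1 + exp(l0 - l1))
}

## Logistic regression: glm.fit; falls back to a tiny-ridge Newton solver
## when the fit is rank-deficient or does not converge (e.g. complete
## separation in small folds).
fit_logistic <- function(x, y, ridge = 1e-6) {
  X <- cbind(1, x)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (!is.null(fit) && !anyNA(fit$coefficients) && fit$converged) {
    return(fit$coefficients)
  }
  beta <- rep(0, ncol(X))
  for (it in 1:25) {
    eta <- as.vector(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + diag(ridge, ncol(X))
    g <- crossprod(X, y - p) - ridge * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}
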