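# Repeated stratified cross-validation and the three classifiers.

## A linearly separable toy score pool.
separable_pool <- function(n = 40, seed = 2) {
  set.seed(seed)
  labels <- rep(0:1, each = n / 2)
  x <- cbind(PC1 = labels * 4 + rnorm(n, sd = 0.2), PC2 = rnorm(n))
  list(x = x, labels = labels)
}

test_that("cross-validation is a pure function of data, config and seed", {
  p <- separable_pool()
  cv <- cv_config(4, 5, base_seed = 3)
  r1 <- cross_validate(p$x, p$labels, classifier_spec("RF"), cv)
  r2 <- cross_validate(p$x, p$labels, classifier_spec("RF"), cv)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$scores, r2$scores)
  r3 <- cross_validate(p$x, p$labels, classifier_spec("RF"),
                       cv_config(4, 5, base_seed = 4))
  expect_false(identical(r1$scores, r3$scores))
})

test_that("every classifier separates the separable pool perfectly", {
  p <- separable_pool()
  for (kind in c("RF", "NB", "GLM")) {
    res <- cross_validate(p$x, p$labels, classifier_spec(kind),
                          cv_config(3, 5, base_seed = 1), cols = "PC1")
    expect_equal(res$summary[["auc_median"]], 100, info = kind)
    expect_equal(res$summary[["accuracy_median"]], 100, info = kind)
  }
})

test_that("stratification constraints and degenerate labels error cleanly", {
  p <- separable_pool(20)
  expect_error(cross_validate(p$x, rep(1, 20), classifier_spec("NB"),
                              cv_config(2, 5)), "both classes")
  ## a class smaller than the fold count cannot be stratified
  labs <- c(rep(0, 3), rep(1, 17))
  expect_error(cross_validate(p$x, labs, classifier_spec("NB"),
                              cv_config(2, 10)), "stratified")
  ## every sample is scored exactly once per round
  res <- cross_validate(p$x, p$labels, classifier_spec("GLM"),
                        cv_config(3, 4, base_seed = 7))
  expect_false(anyNA(res$scores))
  expect_equal(dim(res$scores), c(20L, 3L))
})

test_that("internal Gaussian NB matches e1071 on well-behaved data", {
  set.seed(12)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rbinom(60, 1, 0.5)
  x[y == 1, 1] <- x[y == 1, 1] + 1.5
  fit <- cesmrad:::fit_gaussian_nb(x, y)
  mine <- cesmrad:::predict_gaussian_nb(fit, x)
  ## e1071 uses sd with denominator n-1; feed it the same convention
  ref <- e1071::naiveBayes(data.frame(x), factor(y))
  theirs <- predict(ref, data.frame(x), type = "raw")[, "1"]
  expect_equal(mine, unname(theirs), tolerance = 1e-6)
})

test_that("logistic scores align with glm on full-rank designs", {
  set.seed(13)
  x <- matrix(rnorm(50 * 2), 50, 2)
  y <- rbinom(50, 1, plogis(x[, 1]))
  beta <- cesmrad:::fit_logistic(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(beta), unname(coef(ref)), tolerance = 1e-6)
  ## rank-deficient design falls back to the ridge solver without error
  xd <- cbind(x, x[, 1])
  expect_silent(cesmrad:::fit_logistic(xd, y))
})

test_that("null scores give chance-level median AUC", {
  set.seed(14)
  x <- matrix(rnorm(60 * 2), 60, 2)
  colnames(x) <- c("PC1", "PC2")
  labels <- rep(0:1, each = 30)
  res <- cross_validate(x, labels, classifier_spec("GLM"),
                        cv_config(10, 10, base_seed = 5))
  expect_gt(res$summary[["auc_median"]], 35)
  expect_lt(res$summary[["auc_median"]], 65)
})
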