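# Correlation-matrix PCA, retention criterion, projections and loadings.

toy_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  ## third feature orthogonalized against a in-sample, so the correlation
  ## matrix is exactly [[1,1,0],[1,1,0],[0,0,1]]
  b <- rnorm(n)
  r <- residuals(lm(b ~ a))
  cbind(f1 = a, f2 = a, f3 = as.vector(r))
}

test_that("two identical features give eigen-proportions {2/3, 1/3, 0}", {
  fit <- fit_pca(toy_table(), "TOY")
  expect_equal(fit$explained, c(2, 1, 0) / 3, tolerance = 1e-10)
  expect_equal(fit$retained_p, 2L)       # 2/3 < 0.8 < 1
  ## PC1 loads the two correlated features equally, not the independent one
  il <- important_loadings(fit, 1)
  expect_setequal(il$feature, c("f1", "f2"))
  expect_equal(abs(il$loading), rep(1 / sqrt(2), 2), tolerance = 1e-10)
})

test_that("retention rule: smallest p with cumulative proportion > threshold", {
  fit <- fit_pca(toy_table(), "TOY")
  fake <- fit
  fake$explained <- c(0.5, 0.3, 0.2)
  ## cumulative sums 0.5, 0.8, 1.0: 0.8 does not *exceed* the threshold
  expect_equal(select_components(fake, 0.8), 3L)
  expect_equal(select_components(fake, 0.79), 2L)
  expect_equal(select_components(fake, 0.999), 3L)
  fake$explained <- c(1, 0, 0)
  expect_equal(select_components(fake, 0.8), 1L)
  expect_error(select_components(fit, 1.5), "0, 1")
  ## monotone non-decreasing in the threshold
  fake$explained <- c(0.45, 0.25, 0.2, 0.1)
  ps <- vapply(c(0.2, 0.5, 0.7, 0.9, 0.99), function(t)
    select_components(fake, t), integer(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("spectral identities hold and loadings are orthonormal", {
  set.seed(2)
  x <- matrix(rnorm(40 * 6), 40, 6) %*% matrix(rnorm(36), 6, 6)
  colnames(x) <- paste0("v", 1:6)
  fit <- fit_pca(x, "X")
  G <- fit$loadings
  expect_equal(crossprod(G), diag(6), tolerance = 1e-8, ignore_attr = TRUE)
  R <- cor(x)
  expect_equal(G %*% diag(fit$eigenvalues) %*% t(G), R,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(fit$eigenvalues), 6, tolerance = 1e-8)  # trace of R
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
})

test_that("projections use stored standardization and recover variances", {
  set.seed(3)
  x <- matrix(rnorm(50 * 4), 50, 4)
  x[, 2] <- x[, 1] * 2 + rnorm(50, sd = 0.1)
  colnames(x) <- paste0("v", 1:4)
  fit <- fit_pca(x, "X")
  sc <- predict(fit, x, n_components = 4)
  expect_equal(unname(apply(sc, 2, var)), fit$eigenvalues, tolerance = 1e-8)
  ## a row equal to the training mean projects to the origin
  mu <- as.data.frame(t(colMeans(x)))
  expect_equal(as.vector(predict(fit, mu, n_components = 4)), rep(0, 4),
               tolerance = 1e-10)
  ## full-rank round trip: back-rotation reproduces the z-scores
  z <- scale(x)
  expect_equal(sc %*% t(fit$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(predict(fit, as.data.frame(x)[, 1:2]), "lacks")
})

test_that("PCA is invariant to affine rescaling of a feature", {
  x <- toy_table(40, seed = 5)
  fit1 <- fit_pca(x, "A")
  x2 <- x
  x2[, 3] <- x2[, 3] * 1000 + 17
  fit2 <- fit_pca(x2, "A")
  expect_equal(fit1$eigenvalues, fit2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(fit1$loadings), abs(fit2$loadings), tolerance = 1e-10)
  expect_equal(fit1$retained_p, fit2$retained_p)
})

test_that("wide data (m > n) matches the explicit eigen route", {
  set.seed(6)
  x <- matrix(rnorm(10 * 30), 10, 30)
  colnames(x) <- paste0("v", 1:30)
  fit <- fit_pca(x, "WIDE")
  expect_equal(sum(fit$eigenvalues), 30, tolerance = 1e-8)
  R <- cor(x)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$eigenvalues, ev[seq_along(fit$eigenvalues)],
               tolerance = 1e-8)
  expect_equal(crossprod(fit$loadings),
               diag(ncol(fit$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are handled as documented", {
  x <- cbind(a = rep(1, 10), b = rnorm(10))
  expect_warning(fit <- fit_pca(x, "D"), "zero-variance")
  expect_equal(fit$m, 1L)
  expect_equal(fit$explained, 1)      # single nonconstant feature
  expect_equal(fit$retained_p, 1L)
  expect_error(suppressWarnings(fit_pca(cbind(a = rep(1, 10)), "D")),
               "constant")
  expect_error(fit_pca(toy_table(2), "D"), "3 rows")
})

test_that("important_loadings ranks, floors and serializes", {
  fit <- fit_pca(toy_table(), "TOY")
  all3 <- important_loadings(fit, 3, max_report = 5, floor = 0)
  expect_equal(nrow(all3), 3L)
  expect_error(important_loadings(fit, 9), "bounds")
  path <- withr::local_tempfile(fileext = ".json")
  write_pca(fit, path)
  back <- read_pca(path)
  expect_equal(back$loadings, fit$loadings, tolerance = 1e-12)
  expect_equal(back$eigenvalues, fit$eigenvalues, tolerance = 1e-12)
  sc1 <- predict(fit, toy_table())
  sc2 <- predict(back, toy_table())
  expect_equal(sc1, sc2, tolerance = 1e-12)
})
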