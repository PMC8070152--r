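# Phantom generator: determinism, class-conditional texture, file layout.

test_that("identical configs give bitwise-identical datasets", {
  cfg <- phantom_config(3, 3, seed = 9)
  d1 <- generate_phantom_dataset(cfg)
  d2 <- generate_phantom_dataset(cfg)
  expect_identical(d1$manifest, d2$manifest)
  for (i in seq_along(d1$pairs)) {
    expect_identical(d1$pairs[[i]]$le, d2$pairs[[i]]$le)
    expect_identical(d1$pairs[[i]]$rc, d2$pairs[[i]]$rc)
  }
})

test_that("datasets of different sizes share their common prefix", {
  small <- generate_phantom_dataset(phantom_config(2, 2, seed = 5))
  big <- generate_phantom_dataset(phantom_config(2, 6, seed = 5))
  for (i in 1:4) {
    expect_identical(small$pairs[[i]]$le, big$pairs[[i]]$le)
  }
})

test_that("malignant phantoms have higher RC variance at full separation", {
  d <- generate_phantom_dataset(phantom_config(20, 40, seed = 2,
                                               class_separation = 1,
                                               noise_sd = 2))
  v <- vapply(d$pairs, function(p) var(as.vector(p$rc)), numeric(1))
  lab <- d$manifest$label
  expect_gt(mean(v[lab == 1]), mean(v[lab == 0]))
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(0, 0), "n_benign")
  expect_error(phantom_config(side = 4), ">= 8")
  expect_error(phantom_config(class_separation = 1.2), "class_separation")
})

test_that("written phantom datasets round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  d <- generate_phantom_dataset(phantom_config(2, 3, seed = 4))
  write_phantom_dataset(d, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 5L)
  expect_equal(unname(attr(m, "counts")), c(2, 3))
  pairs <- load_dataset(m, dir)
  for (i in seq_along(pairs)) {
    expect_equal(pairs[[i]]$le, d$pairs[[i]]$le, ignore_attr = TRUE)
    expect_equal(pairs[[i]]$rc, d$pairs[[i]]$rc, ignore_attr = TRUE)
  }
})

test_that("downstream separability rises with class_separation (scaled check)", {
  ## median CV AUC of a logistic model on STAT features, averaged over
  ## seeds, is non-decreasing across separation levels 0 / 0.5 / 1
  mean_auc <- function(sep) {
    aucs <- vapply(1:4, function(seed) {
      d <- generate_phantom_dataset(phantom_config(10, 10, seed = seed,
                                                   class_separation = sep))
      x <- t(vapply(d$pairs, function(p)
        c(stat_features(p$le, "LE"), stat_features(p$rc, "RC")),
        numeric(22)))
      fit <- suppressWarnings(fit_pca(x, "STAT"))
      sc <- predict(fit, as.data.frame(x), n_components = 2)
      cv <- cross_validate(sc, d$manifest$label, classifier_spec("GLM"),
                           cv_config(3, 5, base_seed = seed))
      cv$summary[["auc_median"]]
    }, numeric(1))
    mean(aucs)
  }
  a <- vapply(c(0, 0.5, 1), mean_auc, numeric(1))
  expect_gt(a[2], a[1] - 5)   # allow Monte-Carlo slack at adjacent levels
  expect_gt(a[3], a[2] - 5)
  expect_gt(a[3], a[1])       # strict rise over the full range
})
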