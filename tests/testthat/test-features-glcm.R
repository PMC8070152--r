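# Co-occurrence matrices and the 13 texture descriptors.

worked_band <- rbind(c(0, 0, 1, 1),
                     c(0, 0, 1, 1),
                     c(0, 2, 2, 2),
                     c(2, 2, 3, 3))

test_that("distance-2 horizontal counts match the hand enumeration", {
  spec <- glcm_spec(levels = 4, distance = 2, symmetric = FALSE,
                    normalized = FALSE)
  m <- glcm_matrix(worked_band, spec, "dir1")
  expect_equal(m["0", "1"], 4)
  expect_equal(m["0", "2"], 1)
  expect_equal(m["2", "2"], 1)
  expect_equal(m["2", "3"], 2)
  expect_equal(sum(m), 8)
  expect_equal(unname(m), oracle_glcm_counts(worked_band, 4, 0, 2),
               ignore_attr = TRUE)
})

test_that("all four directions match the enumeration oracle", {
  set.seed(3)
  band <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
  offsets <- list(dir1 = c(0, 2), dir2 = c(-2, 2), dir3 = c(-2, 0),
                  dir4 = c(-2, -2))
  spec <- glcm_spec(symmetric = FALSE, normalized = FALSE)
  for (dir in names(offsets)) {
    o <- offsets[[dir]]
    expect_equal(unname(glcm_matrix(band, spec, dir)),
                 oracle_glcm_counts(band, 8, o[1], o[2]),
                 info = dir, ignore_attr = TRUE)
  }
})

test_that("symmetric accumulation and normalization behave as stated", {
  set.seed(4)
  band <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
  spec <- glcm_spec()
  for (dir in c("dir1", "dir2", "dir3", "dir4")) {
    m <- glcm_matrix(band, spec, dir)
    expect_equal(m, t(m), tolerance = 1e-12)   # symmetry by construction
    expect_equal(sum(m), 1, tolerance = 1e-12) # joint probabilities
  }
  expect_error(glcm_matrix(matrix(0L, 2, 2), glcm_spec(), "dir1"),
               "too small")
})

test_that("constant band yields the single-cell co-occurrence matrix", {
  m <- glcm_matrix(matrix(0L, 6, 6), glcm_spec(), "dir1")
  expect_equal(sum(m), 1)
  expect_equal(m["0", "0"], 1)
  d <- glcm_descriptors(m)
  expect_equal(unname(d["Energy"]), 1)
  expect_equal(unname(d["Entropy"]), 0)
  expect_equal(unname(d["Contrast"]), 0)
  expect_equal(unname(d["Dissimilarity"]), 0)
  expect_equal(unname(d["Homogeneity"]), 1)
  expect_equal(unname(d["Correlation"]), 0)  # zero marginal variance
})

test_that("all 13 descriptors agree with the cell-loop oracle", {
  set.seed(5)
  for (rep in 1:3) {
    band <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    m <- glcm_matrix(band, glcm_spec(), sample(paste0("dir", 1:4), 1))
    got <- glcm_descriptors(m)
    expect_equal(got, oracle_glcm_descriptors(m), tolerance = 1e-10)
  }
  expect_error(glcm_descriptors(matrix(1, 2, 2)), "normalized")
})

test_that("quantization is equal-width over the band's own range", {
  band <- matrix(seq(-3, 3, length.out = 64), 8, 8)
  q <- glcm_quantize(band, 8)
  expect_equal(range(q), c(0, 7))
  expect_true(all(diff(tabulate(as.vector(q) + 1, 8)) == 0))  # 8 per level
  expect_true(all(glcm_quantize(matrix(2.5, 5, 5), 8) == 0))
})

test_that("GLCM set: 312 features over detail bands, directions and views", {
  pair <- fixture_pair()
  f <- glcm_features(pair)
  expect_length(f, 312L)
  expect_true(all(grepl("^(LE|RC)_.+_(HL1|LH1|HH1)_dir[1-4]$", names(f))))
  ## compositional check of one cell of the pipeline
  band <- haar_decompose(pair$rc)$HH1
  q <- glcm_quantize(band, 8)
  d <- glcm_descriptors(glcm_matrix(q, glcm_spec(), "dir2"))
  expect_equal(unname(f["RC_SumEntropy_HH1_dir2"]), unname(d["SumEntropy"]),
               tolerance = 1e-12)
})

test_that("transposition maps dir1 features onto dir3 features", {
  pair <- fixture_pair(side = 12, seed = 7)
  tpair <- roi_pair("t", t(pair$le), t(pair$rc))
  f <- glcm_features(pair)
  ft <- glcm_features(tpair)
  ## transposing the image swaps rows/columns: 0-degree offsets become
  ## 90-degree offsets and the Haar HL/LH bands swap roles
  swap <- function(nm) {
    nm <- sub("_dir1$", "_tmp", nm); nm <- sub("_dir3$", "_dir1", nm)
    nm <- sub("_tmp$", "_dir3", nm)
    nm <- sub("_HL1_", "_tmpB_", nm); nm <- sub("_LH1_", "_HL1_", nm)
    sub("_tmpB_", "_LH1_", nm)
  }
  names(ft) <- swap(names(ft))
  expect_equal(ft[names(f)], f, tolerance = 1e-10)
})
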