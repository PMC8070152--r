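# Manifest handling, label mapping and image-pair loading.

make_manifest_df <- function(n_benign, n_malignant) {
  n <- n_benign + n_malignant
  data.frame(
    lesion_id = sprintf("L%02d", seq_len(n)),
    patient_id = sprintf("P%02d", seq_len(n)),
    birads = c(rep(2:3, length.out = n_benign),
               rep(4:5, length.out = n_malignant)),
    le_path = sprintf("L%02d_LE.png", seq_len(n)),
    rc_path = sprintf("L%02d_RC.png", seq_len(n)),
    stringsAsFactors = FALSE)
}

test_that("manifest read derives labels and class counts from BIRADS", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_manifest_df(15, 43)   # 58-ROI composition
  write.csv(df, path, row.names = FALSE)
  m <- read_manifest(path)
  expect_equal(unname(attr(m, "counts")), c(15, 43))
  expect_equal(m$label, as.integer(df$birads >= 4))
  expect_equal(m$label[df$birads == 4][1], 1L)
  ## order-preserving and idempotent through a write/read round trip
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path2)
  m2 <- read_manifest(path2)
  expect_equal(as.data.frame(m2), as.data.frame(m))
})

test_that("manifest format and label errors are reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_manifest_df(2, 2)
  write.csv(df[, -3], path, row.names = FALSE)           # drop birads
  expect_error(read_manifest(path), "birads")
  df$birads[3] <- 7L
  write.csv(df, path, row.names = FALSE)
  expect_error(read_manifest(path), "row\\(s\\): 3")
  write.csv(df[0, ], path, row.names = FALSE)            # empty record list
  expect_error(read_manifest(path), "no records")
  df <- make_manifest_df(2, 2)
  df$extra <- "x"
  write.csv(df, path, row.names = FALSE)
  expect_warning(read_manifest(path), "extra")
})

test_that("ROI pairs load from PNG with preserved bit depth, reject bad input", {
  dir <- withr::local_tempdir()
  le <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
  rc <- matrix(sample(0:255, 48 * 56, replace = TRUE), 48)   # dims may differ
  png::writePNG(le / 255, file.path(dir, "a_LE.png"))
  png::writePNG(rc / 255, file.path(dir, "a_RC.png"))
  rec <- list(lesion_id = "a", le_path = file.path(dir, "a_LE.png"),
              rc_path = file.path(dir, "a_RC.png"))
  p <- load_roi_pair(rec)
  expect_s3_class(p, "roi_pair")
  expect_equal(p$bit_depth, 8L)
  expect_equal(p$le, matrix(as.numeric(le), 64), ignore_attr = TRUE)
  expect_equal(dim(p$rc), c(48, 56))

  ## 16-bit TIFF round trip preserves depth
  v16 <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64)
  tiff::writeTIFF(v16 / 65535, file.path(dir, "b.tif"), bits.per.sample = 16)
  r <- cesmrad:::read_gray_raster(file.path(dir, "b.tif"))
  expect_equal(r$bit_depth, 16L)
  expect_equal(r$pixels, matrix(as.numeric(v16), 64), ignore_attr = TRUE)

  ## RGB rejected
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  png::writePNG(rgb, file.path(dir, "rgb.png"))
  rec$le_path <- file.path(dir, "rgb.png")
  expect_error(load_roi_pair(rec), "single-channel")

  ## too small for two Haar levels + distance-2 co-occurrence offsets
  tiny <- matrix(sample(0:255, 16, replace = TRUE), 4)
  png::writePNG(tiny / 255, file.path(dir, "tiny.png"))
  rec$le_path <- file.path(dir, "tiny.png")
  expect_error(load_roi_pair(rec), ">= 8")
})

test_that("roi_pair validates intensity range and integrality", {
  ok <- matrix(0:63, 8, 8)
  expect_error(roi_pair("x", ok - 1, ok), "outside")
  expect_error(roi_pair("x", ok + 0.5, ok), "integer")
  expect_error(roi_pair("x", ok + 250, ok), "outside")
  expect_silent(roi_pair("x", ok + 250, ok, bit_depth = 16L))
})
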