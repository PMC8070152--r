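# Seeded texture phantoms: synthetic LE/RC pairs with class-conditional
# texture so the whole pipeline is exercisable without clinical images.

#' Phantom dataset configuration
#'
#' @param n_benign,n_malignant number of phantoms per class.
#' @param side image side in pixels (square phantoms), at least 8.
#' @param seed top-level integer seed; each lesion draws from its own
#'   counter-derived substream, so datasets of different sizes share their
#'   common prefix.
#' @param class_separation effect size in `[0,1]`. At 0 the two class
#'   distributions are identical; at 1 the malignant class has a shorter
#'   correlation length, higher contrast, and a brighter, boundary-perturbed
#'   focal blob on the RC image.
#' @param noise_sd pixel noise standard deviation in gray levels.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_benign = 15L, n_malignant = 43L, side = 64L,
                           seed = 1L, class_separation = 1, noise_sd = 5) {
  stopifnot(n_benign >= 0, n_malignant >= 0, n_benign + n_malignant >= 1)
  if (side < 8L) stop("phantom side must be >= 8 pixels", call. = FALSE)
  stopifnot(class_separation >= 0, class_separation <= 1, noise_sd >= 0)
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 side = as.integer(side), seed = as.integer(seed),
                 class_separation = class_separation, noise_sd = noise_sd),
            class = "phantom_config")
}

## Isotropic Gaussian random field: FFT-filtered white noise with power-law
## spectrum |f|^-beta, standardized to mean 0, sd 1.
gaussian_random_field <- function(side, beta) {
  w <- matrix(rnorm(side * side), side, side)
  f1 <- c(0:floor(side / 2), -(ceiling(side / 2) - 1):-1)[1:side] / side
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  amp <- fr
  amp[1, 1] <- Inf
  amp <- amp^(-beta / 2)
  amp[1, 1] <- 0
  field <- Re(fft(fft(w) * amp, inverse = TRUE)) / (side * side)
  (field - mean(field)) / sd(as.vector(field))
}

## Anisotropic Gaussian blob with optional sinusoidal boundary perturbation
## (irregular margin), unit peak amplitude.
phantom_blob <- function(side, irregularity) {
  cx <- side / 2 + runif(1, -side / 8, side / 8)
  cy <- side / 2 + runif(1, -side / 8, side / 8)
  sx <- side / 6 * runif(1, 0.7, 1.3)
  sy <- side / 6 * runif(1, 0.7, 1.3)
  ang <- runif(1, 0, pi)
  k <- sample(3:6, 1)
  ph <- runif(1, 0, 2 * pi)
  xs <- matrix(rep(seq_len(side), each = side), side) - cx
  ys <- matrix(rep(seq_len(side), times = side), side) - cy
  u <- cos(ang) * xs + sin(ang) * ys
  v <- -sin(ang) * xs + cos(ang) * ys
  theta <- atan2(v, u)
  ## modulate the effective radius to cut lobes into the margin
  mod <- 1 + irregularity * 0.45 * sin(k * theta + ph)
  exp(-0.5 * ((u / (sx * mod))^2 + (v / (sy * mod))^2))
}

## Render one LE/RC pair for a class at a given separation.
render_phantom <- function(side, malignant, s, noise_sd) {
  ## benign reference texture: smooth (beta 3), low contrast, soft RC blob
  beta <- 3 - if (malignant) 1.6 * s else 0
  contrast <- 12 + if (malignant) 10 * s else 0
  blob_amp <- 25 + if (malignant) 70 * s else 0
  irregular <- if (malignant) s else 0
  quantize <- function(x) {
    x <- x + rnorm(length(x), 0, noise_sd)
    matrix(pmin(255L, pmax(0L, as.integer(round(x)))), side, side)
  }
  le <- 120 + contrast * gaussian_random_field(side, beta) +
    0.35 * blob_amp * phantom_blob(side, irregular)
  rc <- 110 + contrast * gaussian_random_field(side, beta) +
    blob_amp * phantom_blob(side, irregular)
  list(le = quantize(le), rc = quantize(rc))
}

#' Generate a seeded phantom dataset in memory
#'
#' Benign phantoms are smooth, low-contrast random fields with a weak RC
#' enhancement focus; malignant phantoms shorten the field's correlation
#' length (more high-frequency texture on both views), raise contrast, and
#' superpose a bright irregular blob on the RC view. The class signal
#' therefore lives in exactly the statistic families the extractors measure
#' (variance, entropy, smoothness, wavelet detail energy, co-occurrence
#' contrast). With `class_separation = 0` the two classes are drawn from the
#' same distribution.
#'
#' @param config a [phantom_config()].
#' @return list with `manifest` (a `cesm_manifest`; image paths filled in by
#'   [write_phantom_dataset()]) and `pairs` (list of [roi_pair()]).
#' @export
#' @examples
#' d <- generate_phantom_dataset(phantom_config(3, 3, seed = 7))
#' d$manifest
generate_phantom_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_benign + config$n_malignant
  labels <- rep(c(0L, 1L), c(config$n_benign, config$n_malignant))
  ids <- sprintf("phantom_%03d", seq_len(n))
  ## every 5th lesion shares its patient with the previous one, mirroring
  ## patients owning several ROIs
  pat_idx <- seq_len(n) - cumsum(seq_len(n) %% 5L == 0L)
  pairs <- vector("list", n)
  birads <- integer(n)
  for (i in seq_len(n)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(derive_seed(config$seed, i))
    img <- render_phantom(config$side, labels[i] == 1L,
                          config$class_separation, config$noise_sd)
    birads[i] <- if (labels[i] == 1L) sample(4:5, 1) else sample(2:3, 1)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pairs[[i]] <- roi_pair(ids[i], img$le, img$rc, bit_depth = 8L)
  }
  manifest <- as_manifest(data.frame(
    lesion_id = ids,
    patient_id = sprintf("patient_%03d", pat_idx),
    birads = birads,
    le_path = paste0(ids, "_LE.png"),
    rc_path = paste0(ids, "_RC.png"),
    stringsAsFactors = FALSE))
  list(manifest = manifest, pairs = pairs)
}

#' Write a phantom dataset to disk as PNGs plus a manifest CSV
#'
#' Produces exactly the layout [read_manifest()] and [load_dataset()] read
#' back.
#'
#' @param dataset result of [generate_phantom_dataset()].
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in dataset$pairs) {
    png::writePNG(p$le / 255, file.path(dir, paste0(p$lesion_id, "_LE.png")))
    png::writePNG(p$rc / 255, file.path(dir, paste0(p$lesion_id, "_RC.png")))
  }
  write_manifest(dataset$manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
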