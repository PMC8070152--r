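# COUNT set: keypoint/blob detection counts (5 detectors x 2 views = 10).
# All detectors run on the image contrast-stretched to 8-bit, with frozen
# parameters documented on each detector. Counts, not descriptors, are the
# features.

count_feature_names <- c("Sift", "MinimumEigenvalue", "Fast", "Brisk", "MSER")

## Bresenham circle of radius 3: the 16 (row, col) offsets used by the FAST
## segment test, in circular order.
fast_circle <- rbind(
  c(-3, 0), c(-3, 1), c(-2, 2), c(-1, 3), c(0, 3), c(1, 3), c(2, 2), c(3, 1),
  c(3, 0), c(3, -1), c(2, -2), c(1, -3), c(0, -3), c(-1, -3), c(-2, -2),
  c(-3, -1))

## FAST-9 segment-test corners with a 3x3 non-max suppression on the
## standard corner score (sum of absolute excesses over the threshold along
## the contiguous arc direction). Returns the score matrix (0 = no corner).
fast_score_matrix <- function(img8, threshold = 20) {
  nr <- nrow(img8); nc <- ncol(img8)
  if (nr < 7L || nc < 7L) return(matrix(0, nr, nc))
  ir <- 4:(nr - 3); ic <- 4:(nc - 3)
  center <- img8[ir, ic, drop = FALSE]
  n <- length(center)
  circ <- matrix(0, n, 16L)
  for (k in 1:16) {
    circ[, k] <- as.vector(img8[ir + fast_circle[k, 1], ic + fast_circle[k, 2],
                                drop = FALSE])
  }
  cen <- as.vector(center)
  bright <- circ > cen + threshold
  dark <- circ < cen - threshold
  arc9 <- function(m) {
    ## TRUE where some arc of 9 contiguous circle points is all TRUE
    hit <- rep(FALSE, nrow(m))
    for (s in 1:16) {
      idx <- ((s - 1L + 0:8) %% 16L) + 1L
      hit <- hit | (rowSums(m[, idx, drop = FALSE]) == 9L)
    }
    hit
  }
  corner <- arc9(bright) | arc9(dark)
  score <- rep(0, n)
  if (any(corner)) {
    exc <- pmax(circ - cen - threshold, cen - circ - threshold, 0)
    score[corner] <- rowSums(exc)[corner]
  }
  out <- matrix(0, nr, nc)
  out[ir, ic] <- matrix(score, length(ir), length(ic))
  out
}

detect_fast <- function(img8, threshold = 20) {
  sum(nonmax_suppress_3x3(fast_score_matrix(img8, threshold)))
}

## Shi-Tomasi minimum-eigenvalue corners: Sobel structure tensor smoothed by
## a Gaussian window (sigma 1.5), corners where the smaller eigenvalue
## exceeds quality x max over the image, 3x3 non-max suppression.
detect_min_eigen <- function(img8, quality = 0.01, sigma = 1.5) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ix <- conv2_sym(img8 / 255, kx)
  iy <- conv2_sym(img8 / 255, t(kx))
  sxx <- gaussian_blur(ix * ix, sigma)
  syy <- gaussian_blur(iy * iy, sigma)
  sxy <- gaussian_blur(ix * iy, sigma)
  lmin <- (sxx + syy) / 2 - sqrt(((sxx - syy) / 2)^2 + sxy^2)
  mx <- max(lmin)
  if (mx <= 0) return(0L)
  score <- lmin
  score[score < quality * mx] <- 0
  sum(nonmax_suppress_3x3(score))
}

## SIFT-style keypoints: difference-of-Gaussian scale-space extrema. Two
## octaves, three intervals; 26-neighbour extremum test on the interior DoG
## levels, contrast threshold 0.03 (on intensities in [0,1]) and principal
## curvature (edge) rejection with r = 10.
detect_sift <- function(img8, contrast_thr = 0.03, edge_r = 10) {
  img <- img8 / 255
  total <- 0L
  k <- 2^(1 / 3)
  for (octave in 1:2) {
    if (nrow(img) < 8L || ncol(img) < 8L) break
    sigmas <- 1.6 * k^(0:4)
    gs <- lapply(sigmas, function(s) gaussian_blur(img, s))
    dog <- lapply(1:4, function(t) gs[[t + 1]] - gs[[t]])
    nr <- nrow(img); nc <- ncol(img)
    for (lev in 2:3) {
      d <- dog[[lev]]
      cand <- which(abs(d) > contrast_thr &
                      row(d) > 1 & row(d) < nr & col(d) > 1 & col(d) < nc)
      for (idx in cand) {
        r <- (idx - 1L) %% nr + 1L
        c <- (idx - 1L) %/% nr + 1L
        v <- d[r, c]
        nb <- c(d[(r - 1):(r + 1), (c - 1):(c + 1)],
                dog[[lev - 1]][(r - 1):(r + 1), (c - 1):(c + 1)],
                dog[[lev + 1]][(r - 1):(r + 1), (c - 1):(c + 1)])
        if ((v > 0 && v >= max(nb)) || (v < 0 && v <= min(nb))) {
          ## reject edge responses via the DoG Hessian curvature ratio
          dxx <- d[r, c + 1] + d[r, c - 1] - 2 * v
          dyy <- d[r + 1, c] + d[r - 1, c] - 2 * v
          dxy <- (d[r + 1, c + 1] - d[r + 1, c - 1] -
                    d[r - 1, c + 1] + d[r - 1, c - 1]) / 4
          tr <- dxx + dyy
          det <- dxx * dyy - dxy^2
          if (det > 0 && tr^2 / det < (edge_r + 1)^2 / edge_r) {
            total <- total + 1L
          }
        }
      }
    }
    ## next octave: blur then take every second pixel
    base <- gs[[4]]
    img <- base[seq(1, nrow(base), by = 2), seq(1, ncol(base), by = 2),
                drop = FALSE]
  }
  total
}

## BRISK-style detector: the FAST-9 segment test applied on a 3-layer
## scale pyramid (scales 1, 2, 4 by local 2x2 averaging), counts summed
## with in-layer non-max suppression.
detect_brisk <- function(img8, threshold = 20) {
  total <- 0L
  img <- img8
  for (layer in 1:3) {
    if (nrow(img) < 12L || ncol(img) < 12L) break
    total <- total + detect_fast(img, threshold)
    nr2 <- floor(nrow(img) / 2); nc2 <- floor(ncol(img) / 2)
    img <- (img[seq(1, 2 * nr2, by = 2), seq(1, 2 * nc2, by = 2), drop = FALSE] +
            img[seq(2, 2 * nr2, by = 2), seq(1, 2 * nc2, by = 2), drop = FALSE] +
            img[seq(1, 2 * nr2, by = 2), seq(2, 2 * nc2, by = 2), drop = FALSE] +
            img[seq(2, 2 * nr2, by = 2), seq(2, 2 * nc2, by = 2), drop = FALSE]) / 4
  }
  total
}

## Maximally stable extremal regions, counted over both polarities.
## Threshold sweep with step delta = 5 gray levels; connected components
## (8-connectivity) labelled per threshold; a region at threshold t is
## stable when its forward relative growth (area at t+delta over area at t,
## matched through a representative pixel) is below max_variation and is a
## local minimum along the sweep. Area bounds [20, 0.4 * npixels].
detect_mser_one <- function(img8, delta = 5, max_variation = 0.25,
                            min_area = 20, max_area_frac = 0.4) {
  nr <- nrow(img8); nc <- ncol(img8)
  npix <- nr * nc
  thresholds <- seq(0, 250, by = delta)
  nlev <- length(thresholds)
  labels <- vector("list", nlev)
  for (k in seq_len(nlev)) {
    bw <- img8 <= thresholds[k]
    labels[[k]] <- if (any(bw)) {
      EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1, dim(bw))))
    } else matrix(0L, nr, nc)
  }
  ## per level: component areas and a representative pixel (lowest index)
  comp_info <- lapply(labels, function(L) {
    v <- as.vector(L)
    pos <- v > 0
    if (!any(pos)) return(NULL)
    areas <- tabulate(v[pos])
    reps <- vapply(seq_along(areas), function(id) match(id, v), integer(1))
    list(areas = areas, reps = reps)
  })
  variation <- vector("list", nlev)
  for (k in seq_len(nlev - 1)) {
    ci <- comp_info[[k]]
    if (is.null(ci)) next
    nxt <- labels[[k + 1]]
    parent_area <- vapply(ci$reps, function(rp) {
      id <- nxt[rp]
      if (id > 0) comp_info[[k + 1]]$areas[id] else NA_real_
    }, numeric(1))
    variation[[k]] <- (parent_area - ci$areas) / ci$areas
  }
  count <- 0L
  for (k in 2:(nlev - 1)) {
    ci <- comp_info[[k]]
    vk <- variation[[k]]
    if (is.null(ci) || is.null(vk)) next
    for (id in seq_along(ci$areas)) {
      a <- ci$areas[id]
      if (a < min_area || a > max_area_frac * npix) next
      v <- vk[id]
      if (is.na(v) || v > max_variation) next
      ## local minimum of variation vs the matched component one level down
      prev <- labels[[k - 1]][ci$reps[id]]
      vprev <- if (prev > 0 && !is.null(variation[[k - 1]]))
        variation[[k - 1]][prev] else Inf
      vnext <- {
        nid <- labels[[k + 1]][ci$reps[id]]
        if (k + 1 <= nlev - 1 && nid > 0 && !is.null(variation[[k + 1]]))
          variation[[k + 1]][nid] else Inf
      }
      if (!is.na(vprev) && !is.na(vnext) && v <= vprev && v <= vnext) {
        count <- count + 1L
      }
    }
  }
  count
}

detect_mser <- function(img8, ...) {
  detect_mser_one(img8, ...) + detect_mser_one(255L - img8, ...)
}

#' Keypoint-count features of a gray-level image
#'
#' Runs five detectors with frozen parameters on the image
#' contrast-stretched to 8-bit and returns each detector's number of
#' detections: a SIFT-style difference-of-Gaussian extremum detector, the
#' Shi-Tomasi minimum-eigenvalue corner detector, the FAST-9 segment-test
#' corner detector, a BRISK-style multi-scale FAST detector, and an MSER
#' blob detector. A constant image yields five zeros.
#'
#' @param image integer-valued intensity matrix.
#' @param prefix name prefix, `"LE"` or `"RC"`.
#' @return named numeric vector
#'   `{Sift, MinimumEigenvalue, Fast, Brisk, MSER}`.
#' @export
count_features <- function(image, prefix = "") {
  img8 <- stretch_to_8bit(image)
  if (all(img8 == 0L)) {
    out <- c(Sift = 0, MinimumEigenvalue = 0, Fast = 0, Brisk = 0, MSER = 0)
  } else {
    out <- c(Sift = detect_sift(img8),
             MinimumEigenvalue = detect_min_eigen(img8),
             Fast = detect_fast(img8),
             Brisk = detect_brisk(img8),
             MSER = detect_mser(img8))
  }
  if (nzchar(prefix)) names(out) <- paste(prefix, names(out), sep = "_")
  out
}
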