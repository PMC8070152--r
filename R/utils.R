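# Internal numeric helpers shared by the feature extractors.

## Half-sample symmetric (reflective) index for arbitrary out-of-range
## positions: ... 2 1 | 1 2 .. n n | n n-1 ...
reflect_index <- function(i, n) {
  m <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n) + 1
  ifelse(m > n, 2 * n + 1 - m, m)
}

## Symmetric padding of a matrix by `p` pixels on every side; reflection is
## repeated as needed, so p may exceed the image dimension.
pad_symmetric <- function(x, p) {
  stopifnot(p >= 0)
  if (p == 0) return(x)
  x[reflect_index((1 - p):(nrow(x) + p), nrow(x)),
    reflect_index((1 - p):(ncol(x) + p), ncol(x)), drop = FALSE]
}

## 2-D convolution with a small odd-sided kernel and symmetric padding.
## Implemented as a sum of shifted submatrices (kernels here are <= 15x15).
conv2_sym <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  p <- max((kr - 1L) %/% 2L, (kc - 1L) %/% 2L)
  xp <- pad_symmetric(x, p)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  r0 <- p + 1L - (kr - 1L) %/% 2L
  c0 <- p + 1L - (kc - 1L) %/% 2L
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      k <- kernel[i, j]
      if (k == 0) next
      ## convolution flips the kernel relative to cross-correlation
      out <- out + k * xp[(r0 + kr - i):(r0 + kr - i + nr - 1L),
                          (c0 + kc - j):(c0 + kc - j + nc - 1L), drop = FALSE]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian blur with symmetric padding.
gaussian_blur <- function(x, sigma) {
  k <- gaussian_kernel_1d(sigma)
  conv2_sym(conv2_sym(x, matrix(k, nrow = 1)), matrix(k, ncol = 1))
}

## Population central moments: mean, variance (divide by N), skewness
## m3/m2^{3/2} and kurtosis m4/m2^2 (non-excess). Skewness and kurtosis of a
## constant sample are defined as 0 so flat ROIs remain representable.
population_moments <- function(v) {
  n <- length(v)
  mu <- mean(v)
  d <- v - mu
  m2 <- sum(d^2) / n
  if (m2 <= 0) {
    return(list(mean = mu, var = 0, sd = 0, skew = 0, kurt = 0))
  }
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  list(mean = mu, var = m2, sd = sqrt(m2),
       skew = m3 / m2^1.5, kurt = m4 / m2^2)
}

## Shannon entropy in bits of a probability vector; empty bins contribute 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

## Entropy of an integer-valued image from its native gray-level histogram.
entropy_integer_image <- function(x) {
  counts <- table(as.vector(x))
  entropy_bits(as.numeric(counts) / length(x))
}

## Entropy of a continuous-valued map: 256 equal-width bins over the
## observed range; a constant map has a single occupied bin, entropy 0.
entropy_continuous_map <- function(x, nbins = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  bins <- floor((v - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L
  bins[bins > nbins] <- nbins
  entropy_bits(tabulate(bins, nbins) / length(v))
}

## Contrast-stretch any numeric matrix to integer 0..255 (flat input -> 0).
stretch_to_8bit <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(x), ncol(x)))
  matrix(as.integer(round((x - rng[1]) / (rng[2] - rng[1]) * 255)),
         nrow(x), ncol(x))
}

## 3x3 non-maximum suppression on a score matrix: TRUE where the score is
## positive and strictly greater than (or equal with earliest index winning
## via strict comparison on shifted copies) its 8 neighbours.
nonmax_suppress_3x3 <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- score
  keep <- score > 0
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      keep <- keep & (score >= pad[(2 + dr):(nr + 1 + dr),
                                   (2 + dc):(nc + 1 + dc)])
    }
  }
  ## break plateau ties: require strict superiority over neighbours that
  ## precede in column-major order
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dc < 0 || (dc == 0 && dr < 0)) {
        keep <- keep & (score > pad[(2 + dr):(nr + 1 + dr),
                                    (2 + dc):(nc + 1 + dc)])
      }
    }
  }
  keep
}

## Deterministic per-item substream seed derived from a base seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
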