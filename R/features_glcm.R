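# GLCM set: gray-level co-occurrence matrices on the first-level Haar
# detail bands and 13 texture descriptors (312 per pair).

#' Co-occurrence matrix specification
#'
#' @param levels number of quantized gray levels (default 8).
#' @param distance pixel offset distance D (default 2).
#' @param symmetric count each pixel pair in both orders (default TRUE).
#' @param normalized divide counts by their total so the matrix is a joint
#'   probability distribution (default TRUE).
#' @return a `glcm_spec` list. The four offset directions are fixed at
#'   0, 45, 90 and 135 degrees (`dir1..dir4`).
#' @export
glcm_spec <- function(levels = 8L, distance = 2L, symmetric = TRUE,
                      normalized = TRUE) {
  stopifnot(levels >= 2L, distance >= 1L)
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 symmetric = isTRUE(symmetric), normalized = isTRUE(normalized)),
            class = "glcm_spec")
}

## (row, col) offsets for dir1..dir4 = 0, 45, 90, 135 degrees at distance D
## (rows grow downward, so +45 degrees moves up and right).
glcm_offsets <- function(d) {
  list(dir1 = c(0L, d), dir2 = c(-d, d), dir3 = c(-d, 0L), dir4 = c(-d, -d))
}

#' Quantize a band to equal-width gray levels
#'
#' Equal-width binning over the band's own observed min-max range; a
#' constant band maps entirely to level 0.
#'
#' @param band numeric matrix.
#' @param levels number of levels.
#' @return integer matrix with values in `0..levels-1`.
#' @export
glcm_quantize <- function(band, levels = 8L) {
  rng <- range(band)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(band), ncol(band)))
  q <- floor((band - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q >= levels] <- levels - 1L
  matrix(as.integer(q), nrow(band), ncol(band))
}

#' Accumulate a gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized levels for pixel pairs at the offset
#' given by `spec$distance` and `direction`; element (i, j) is the number of
#' times levels i and j co-occur at that offset. With `spec$symmetric` each
#' pair is also counted in the reverse order; with `spec$normalized` the
#' matrix is divided by its total so it sums to 1.
#'
#' @param band integer matrix of quantized levels in `0..spec$levels-1`
#'   (see [glcm_quantize()]).
#' @param spec a [glcm_spec()].
#' @param direction one of `"dir1".."dir4"` (0, 45, 90, 135 degrees).
#' @return `levels x levels` matrix with dimnames `0..levels-1`.
#' @export
#' @examples
#' band <- rbind(c(0,0,1,1), c(0,0,1,1), c(0,2,2,2), c(2,2,3,3))
#' m <- glcm_matrix(band, glcm_spec(levels = 4, symmetric = FALSE,
#'                                  normalized = FALSE), "dir1")
#' m["0", "1"]  # 4
glcm_matrix <- function(band, spec, direction = "dir1") {
  off <- glcm_offsets(spec$distance)[[direction]]
  if (is.null(off)) stop("unknown direction: ", direction, call. = FALSE)
  nr <- nrow(band); nc <- ncol(band)
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  r2 <- rows + off[1]
  c2 <- cols + off[2]
  rok <- rows[r2 >= 1L & r2 <= nr]
  cok <- cols[c2 >= 1L & c2 <= nc]
  if (length(rok) == 0L || length(cok) == 0L) {
    stop("band too small for offset distance ", spec$distance, call. = FALSE)
  }
  a <- band[rok, cok, drop = FALSE]
  b <- band[rok + off[1], cok + off[2], drop = FALSE]
  L <- spec$levels
  counts <- matrix(tabulate(as.vector(a) * L + as.vector(b) + 1L, L * L),
                   L, L, byrow = TRUE)
  if (spec$symmetric) counts <- counts + t(counts)
  if (spec$normalized) counts <- counts / sum(counts)
  dimnames(counts) <- list(0:(L - 1), 0:(L - 1))
  counts
}

glcm_descriptor_names <- c(
  "Contrast", "Correlation", "ClusterProminence", "ClusterShade",
  "Dissimilarity", "Energy", "Entropy", "Homogeneity", "SumAverage",
  "SumVariance", "SumEntropy", "DifferenceEntropy", "InvDiffMomentNorm")

#' Texture descriptors of a normalized co-occurrence matrix
#'
#' The 13 descriptors: contrast, correlation, cluster prominence, cluster
#' shade, dissimilarity, energy, entropy, homogeneity, sum average, sum
#' variance, sum entropy, difference entropy and normalized inverse
#' difference moment. Levels are indexed 1..N for the moment-style sums;
#' entropies are in bits. Correlation of a degenerate (single-level) matrix
#' is defined as 0 since the marginal variance vanishes.
#'
#' @param p normalized co-occurrence matrix (sums to 1).
#' @return named numeric vector of length 13.
#' @export
glcm_descriptors <- function(p) {
  N <- nrow(p)
  if (abs(sum(p) - 1) > 1e-8) stop("matrix must be normalized", call. = FALSE)
  i <- matrix(rep(seq_len(N), times = N), N)       # row index
  j <- matrix(rep(seq_len(N), each = N), N)        # col index
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j) else 0
  ## diagonal-sum marginals p_{x+y}(k), k = 2..2N and p_{|x-y|}(k), k = 0..N-1
  psum <- vapply(2:(2 * N), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(N - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  sum_avg <- sum((2:(2 * N)) * psum)
  c(Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    ClusterProminence = sum((i + j - mu_i - mu_j)^4 * p),
    ClusterShade = sum((i + j - mu_i - mu_j)^3 * p),
    Dissimilarity = sum(abs(i - j) * p),
    Energy = sum(p^2),
    Entropy = entropy_bits(as.vector(p)),
    Homogeneity = sum(p / (1 + abs(i - j))),
    SumAverage = sum_avg,
    SumVariance = sum(((2:(2 * N)) - sum_avg)^2 * psum),
    SumEntropy = entropy_bits(psum),
    DifferenceEntropy = entropy_bits(pdiff),
    InvDiffMomentNorm = sum(p / (1 + (i - j)^2 / N^2)))
}

glcm_band_names <- c("HL1", "LH1", "HH1")

#' Co-occurrence texture features of an LE/RC pair
#'
#' For each view, each first-level Haar detail band (HL1, LH1, HH1) is
#' quantized to `spec$levels` equal-width levels and its co-occurrence
#' matrix accumulated in the four directions; the 13 descriptors of each
#' normalized matrix give 13 x 4 x 3 x 2 = 312 features, named e.g.
#' `RC_SumEntropy_HH1_dir2`. A degenerate band (a single quantized level)
#' yields the constant-band closed forms (energy 1, entropy 0, contrast 0).
#'
#' @param pair a [roi_pair()].
#' @param spec a [glcm_spec()]; normalization is forced on for descriptor
#'   computation.
#' @return named numeric vector of length 312.
#' @export
glcm_features <- function(pair, spec = glcm_spec()) {
  spec$normalized <- TRUE
  out <- c()
  for (view in c("LE", "RC")) {
    bands <- haar_decompose(pair[[tolower(view)]])
    for (band in glcm_band_names) {
      q <- glcm_quantize(bands[[band]], spec$levels)
      for (dir in names(glcm_offsets(spec$distance))) {
        d <- glcm_descriptors(glcm_matrix(q, spec, dir))
        names(d) <- paste(view, names(d), band, dir, sep = "_")
        out <- c(out, d)
      }
    }
  }
  out
}
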