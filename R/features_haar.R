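# HAAR set: two-level orthonormal Haar decomposition and sub-band
# statistics (96 per pair).

## One orthonormal Haar analysis level along one dimension: pairs
## (x[2k-1], x[2k]) map to approximation (x1+x2)/sqrt(2) and detail
## (x1-x2)/sqrt(2). Odd lengths are symmetrically extended by repeating the
## last sample.
haar_split_rows <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  odd <- x[seq(1, nrow(x), by = 2), , drop = FALSE]
  even <- x[seq(2, nrow(x), by = 2), , drop = FALSE]
  list(lo = (odd + even) / sqrt(2), hi = (odd - even) / sqrt(2))
}

haar_level <- function(x) {
  rows <- haar_split_rows(x)
  lo <- haar_split_rows(t(rows$lo))
  hi <- haar_split_rows(t(rows$hi))
  ## first letter: filter along columns (x), second: along rows (y)
  list(LL = t(lo$lo), HL = t(lo$hi), LH = t(hi$lo), HH = t(hi$hi))
}

haar_band_names <- c("LL1", "HL1", "LH1", "HH1", "LL2", "HL2", "LH2", "HH2")

#' Two-level Haar wavelet decomposition
#'
#' Splits the image into approximation (LL) and horizontal/vertical/diagonal
#' detail bands (HL/LH/HH) with orthonormal Haar filters, then re-decomposes
#' LL1 with the same filters. Each level halves both dimensions; odd sizes
#' are symmetrically extended by one sample. For a constant image of value
#' `v` every detail band is 0 and LL2 is constant `4v` (two x2 scaling
#' stages). On even-sized inputs the level-1 coefficient energy equals the
#' image energy (orthonormality).
#'
#' @param image numeric matrix, at least 8x8.
#' @return named list of the 8 sub-band matrices
#'   `LL1, HL1, LH1, HH1, LL2, HL2, LH2, HH2`.
#' @export
#' @examples
#' b <- haar_decompose(matrix(10, 8, 8))
#' unique(as.vector(b$LL2))   # 40
haar_decompose <- function(image) {
  if (nrow(image) < 8L || ncol(image) < 8L) {
    stop("image must be at least 8x8 for a two-level Haar decomposition",
         call. = FALSE)
  }
  l1 <- haar_level(image)
  l2 <- haar_level(l1$LL)
  out <- list(LL1 = l1$LL, HL1 = l1$HL, LH1 = l1$LH, HH1 = l1$HH,
              LL2 = l2$LL, HL2 = l2$HL, LH2 = l2$LH, HH2 = l2$HH)
  out
}

#' Haar sub-band statistics of an LE/RC pair
#'
#' The same six statistics as [grad_features()], computed on the
#' coefficients of each of the 8 sub-bands of each view:
#' 6 x 8 x {LE, RC} = 96 features, named e.g. `LE_RelativeSmoothness_HL2`.
#'
#' @param pair a [roi_pair()].
#' @return named numeric vector of length 96.
#' @export
haar_stat_features <- function(pair) {
  out <- c()
  for (view in c("LE", "RC")) {
    bands <- haar_decompose(pair[[tolower(view)]])
    for (band in haar_band_names) {
      s <- map_statistics(bands[[band]])
      names(s) <- paste(view, names(s), band, sep = "_")
      out <- c(out, s)
    }
  }
  out
}
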