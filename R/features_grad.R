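# GRAD set: Sobel gradient magnitude/direction statistics (24 per pair).

#' Sobel gradient magnitude and direction maps
#'
#' Convolves the 3x3 Sobel kernels (x increasing along columns, y along
#' rows) with symmetric boundary padding and returns the magnitude
#' `sqrt(Gx^2 + Gy^2)` and direction `atan2(Gy, Gx)` in radians.
#'
#' @param image numeric matrix, at least 3x3.
#' @return list with matrices `gmag` and `gdir`.
#' @export
sobel_gradient <- function(image) {
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("image must be at least 3x3 for Sobel gradients", call. = FALSE)
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  ky <- t(kx)                                               # d/dy (rows)
  gx <- conv2_sym(image, kx)
  gy <- conv2_sym(image, ky)
  list(gmag = sqrt(gx^2 + gy^2), gdir = atan2(gy, gx))
}

#' Gradient-map statistics of an LE/RC pair
#'
#' Six statistics (mean, variance, skewness, entropy, relative smoothness,
#' kurtosis) of the Sobel gradient magnitude and direction of each view:
#' 6 x {Gmag, Gdir} x {LE, RC} = 24 features, named e.g. `RC_Mean_Gmag`,
#' `LE_Skewness_Gdir`. Direction is treated as a plain real in `(-pi, pi]`
#' (no circular statistics).
#'
#' @param pair a [roi_pair()].
#' @return named numeric vector of length 24.
#' @export
grad_features <- function(pair) {
  out <- c()
  for (view in c("LE", "RC")) {
    g <- sobel_gradient(pair[[tolower(view)]])
    for (comp in c("Gmag", "Gdir")) {
      s <- map_statistics(if (comp == "Gmag") g$gmag else g$gdir)
      names(s) <- paste(view, names(s), comp, sep = "_")
      out <- c(out, s)
    }
  }
  out
}
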