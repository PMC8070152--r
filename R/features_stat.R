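# STAT set: 11 first-order gray-level statistics per image (22 per pair).

stat_feature_names <- c("Mean", "Std", "MeanStdRatio", "Variance", "Skewness",
                        "Entropy", "RelativeSmoothness", "Kurtosis", "Min",
                        "Max", "MaxMinusMin")

#' First-order statistics of a gray-level image
#'
#' Computes the 11 histogram statistics of one ROI: mean, standard deviation
#' and their ratio, variance, skewness, entropy, relative smoothness,
#' kurtosis, minimum, maximum and their difference. Moments use the
#' population convention (divide by N). Entropy is in bits from the native
#' gray-level histogram. Relative smoothness is \eqn{1 - 1/(1 + \sigma^2)}
#' with the variance taken on intensities rescaled to `[0,1]` by
#' `2^bit_depth - 1`, which keeps it in `[0,1]`. `MeanStdRatio` is defined as
#' 0 when the standard deviation is 0, so constant ROIs stay representable.
#'
#' @param image integer-valued intensity matrix.
#' @param prefix name prefix, `"LE"` or `"RC"`.
#' @param bit_depth bit depth used for the smoothness normalization.
#' @return named numeric vector of length 11.
#' @export
#' @examples
#' stat_features(matrix(rep(0:7, 8), 8, 8), "LE")["Entropy"]  # 3 bits
stat_features <- function(image, prefix = "", bit_depth = 8L) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  v <- as.vector(image)
  m <- population_moments(v)
  scaled_var <- m$var / (2^bit_depth - 1)^2
  out <- c(Mean = m$mean,
           Std = m$sd,
           MeanStdRatio = if (m$sd > 0) m$mean / m$sd else 0,
           Variance = m$var,
           Skewness = m$skew,
           Entropy = entropy_integer_image(v),
           RelativeSmoothness = 1 - 1 / (1 + scaled_var),
           Kurtosis = m$kurt,
           Min = min(v),
           Max = max(v),
           MaxMinusMin = max(v) - min(v))
  if (nzchar(prefix)) names(out) <- paste(prefix, names(out), sep = "_")
  out
}

## Six distributional statistics reused by the GRAD and HAAR sets, computed
## on continuous-valued maps (gradient magnitude/direction, wavelet bands):
## entropy uses 256 equal-width bins over the observed range, and relative
## smoothness normalizes the values to [0,1] over that same range before
## taking the variance (flat maps give 0).
map_statistics <- function(map) {
  v <- as.vector(map)
  m <- population_moments(v)
  rng <- diff(range(v))
  rs_var <- if (rng > 0) m$var / rng^2 else 0
  c(Mean = m$mean, Variance = m$var, Skewness = m$skew,
    Entropy = entropy_continuous_map(v),
    RelativeSmoothness = 1 - 1 / (1 + rs_var),
    Kurtosis = m$kurt)
}
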