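# Independent brute-force oracles used to pin down the extractors.
# Everything here is written as plain elementwise loops, deliberately
# separate from the package implementations.

oracle_moments <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- m3 <- m4 <- 0
  for (x in v) {
    m2 <- m2 + (x - mu)^2 / n
    m3 <- m3 + (x - mu)^3 / n
    m4 <- m4 + (x - mu)^4 / n
  }
  list(mean = mu, var = m2,
       skew = if (m2 > 0) m3 / m2^1.5 else 0,
       kurt = if (m2 > 0) m4 / m2^2 else 0)
}

oracle_entropy_bits <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi) / log(2)
  h
}

oracle_hist_entropy <- function(v) {
  counts <- table(v)
  oracle_entropy_bits(as.numeric(counts) / length(v))
}

## GLCM counts by explicit pair enumeration; offset in (dr, dc).
oracle_glcm_counts <- function(band, levels, dr, dc) {
  m <- matrix(0, levels, levels)
  for (r in seq_len(nrow(band))) {
    for (c in seq_len(ncol(band))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(band) && c2 >= 1 && c2 <= ncol(band)) {
        i <- band[r, c] + 1L; j <- band[r2, c2] + 1L
        m[i, j] <- m[i, j] + 1
      }
    }
  }
  m
}

## The 13 descriptors by textbook cell loops over the normalized matrix.
oracle_glcm_descriptors <- function(p) {
  N <- nrow(p)
  mu_i <- mu_j <- 0
  for (i in 1:N) for (j in 1:N) { mu_i <- mu_i + i * p[i, j]
                                  mu_j <- mu_j + j * p[i, j] }
  var_i <- var_j <- covar <- 0
  for (i in 1:N) for (j in 1:N) {
    var_i <- var_i + (i - mu_i)^2 * p[i, j]
    var_j <- var_j + (j - mu_j)^2 * p[i, j]
    covar <- covar + (i - mu_i) * (j - mu_j) * p[i, j]
  }
  contrast <- dissim <- energy <- entropy <- homog <- 0
  prom <- shade <- idmn <- 0
  for (i in 1:N) for (j in 1:N) {
    pij <- p[i, j]
    contrast <- contrast + (i - j)^2 * pij
    dissim <- dissim + abs(i - j) * pij
    energy <- energy + pij^2
    if (pij > 0) entropy <- entropy - pij * log2(pij)
    homog <- homog + pij / (1 + abs(i - j))
    prom <- prom + (i + j - mu_i - mu_j)^4 * pij
    shade <- shade + (i + j - mu_i - mu_j)^3 * pij
    idmn <- idmn + pij / (1 + (i - j)^2 / N^2)
  }
  psum <- rep(0, 2 * N - 1)   # k = 2..2N
  pdiff <- rep(0, N)          # k = 0..N-1
  for (i in 1:N) for (j in 1:N) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((2:(2 * N)) * psum)
  sv <- sum(((2:(2 * N)) - sa)^2 * psum)
  c(Contrast = contrast,
    Correlation = if (var_i > 0 && var_j > 0) covar / sqrt(var_i * var_j) else 0,
    ClusterProminence = prom, ClusterShade = shade,
    Dissimilarity = dissim, Energy = energy, Entropy = entropy,
    Homogeneity = homog, SumAverage = sa, SumVariance = sv,
    SumEntropy = oracle_entropy_bits(psum),
    DifferenceEntropy = oracle_entropy_bits(pdiff),
    InvDiffMomentNorm = idmn)
}

## Single-level Haar by explicit 2x2 block sums on even-sized images.
oracle_haar_level <- function(x) {
  nr <- nrow(x) / 2; nc <- ncol(x) / 2
  LL <- HL <- LH <- HH <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    a <- x[2 * r - 1, 2 * c - 1]; b <- x[2 * r - 1, 2 * c]
    d <- x[2 * r, 2 * c - 1];     e <- x[2 * r, 2 * c]
    LL[r, c] <- (a + b + d + e) / 2
    HL[r, c] <- (a - b + d - e) / 2   # high along columns (x)
    LH[r, c] <- (a + b - d - e) / 2   # high along rows (y)
    HH[r, c] <- (a - b - d + e) / 2
  }
  list(LL = LL, HL = HL, LH = LH, HH = HH)
}

## AUC by enumerating all positive/negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

## A small deterministic textured test pair.
fixture_pair <- function(side = 16, seed = 42) {
  set.seed(seed)
  le <- matrix(sample(0:255, side * side, replace = TRUE), side, side)
  rc <- matrix(sample(0:255, side * side, replace = TRUE), side, side)
  roi_pair("fixture", le, rc, bit_depth = 8L)
}
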