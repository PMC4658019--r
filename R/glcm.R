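#' Gray-level co-occurrence matrix of an ROI
#'
#' Quantizes the rescaled `[0, 255]` patch into `levels` gray levels and
#' accumulates symmetric distance-1 co-occurrence counts over the four
#' angular directions (0, 45, 90, 135 degrees). The four matrices are
#' averaged into one and normalized to sum 1, which makes the derived
#' features exactly invariant under 90-degree patch rotation and
#' transposition.
#'
#' @param patch An `roi_patch`.
#' @param levels Number of gray levels (default 16; an 8x8 patch has only
#'   64 pixels, so a dense small matrix beats a sparse 256 x 256 one).
#' @return `levels` x `levels` matrix summing to 1.
#' @export
glcm_matrix <- function(patch, levels = 16L) {
  if (!levels %in% c(8L, 16L, 32L))
    stop("GLCM levels must be one of 8, 16, 32")
  q <- quantize_levels(patch$rescaled, levels)
  # Offsets (drow, dcol) for 0, 45, 90, 135 degrees at distance 1
  # (rows increase downward).
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  acc <- matrix(0, levels, levels)
  for (off in offsets) {
    m <- cooccurrence_counts(q, off[1], off[2], levels)
    m <- m + t(m)                       # symmetric pairs
    acc <- acc + m / sum(m)
  }
  acc / 4
}

quantize_levels <- function(rescaled, levels) {
  # 0..255 -> 1..levels by equal-width bins
  pmin(rescaled %/% (256L %/% levels) + 1L, levels)
}

cooccurrence_counts <- function(q, dr, dc, levels) {
  n <- nrow(q)
  r1 <- max(1, 1 - dr):min(n, n - dr)
  c1 <- max(1, 1 - dc):min(n, n - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  m <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
  m + as.matrix(tab)
}

#' GLCM texture features
#'
#' Computes 13 rotation-invariant features from the direction-averaged
#' co-occurrence matrix: energy (angular second moment), entropy,
#' homogeneity (inverse difference moment), dissimilarity, correlation,
#' contrast, variance, sum average, sum variance, sum entropy, difference
#' variance, difference entropy and the first information measure of
#' correlation. Entropies use the natural logarithm. Correlation and the
#' information measure are defined as 0 for zero-variance (constant)
#' patches.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 13.
#' @export
compute_glcm_features <- function(patch, levels = 16L) {
  p <- glcm_matrix(patch, levels)
  g <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)          # equal by symmetry
  mu_x <- sum(seq_len(g) * px); mu_y <- sum(seq_len(g) * py)
  sd_x <- sqrt(sum((seq_len(g) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(g) - mu_y)^2 * py))

  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }

  energy <- sum(p^2)
  entropy <- ent(p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  dissimilarity <- sum(p * abs(i - j))
  contrast <- sum(p * (i - j)^2)
  correlation <- if (sd_x > 0 && sd_y > 0)
    sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y) else 0
  variance <- sum((i - mu_x)^2 * p)

  # Sum/difference distributions p_{x+y}, p_{x-y}
  psum <- tapply(as.vector(p), as.vector(i + j), sum)      # k = 2..2g
  ks <- as.numeric(names(psum))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- ent(psum)
  pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum) # k = 0..g-1
  kd <- as.numeric(names(pdiff))
  mu_d <- sum(kd * pdiff)
  diff_variance <- sum((kd - mu_d)^2 * pdiff)
  diff_entropy <- ent(pdiff)

  # Information measure of correlation 1
  hx <- ent(px); hy <- ent(py)
  hxy1 <- { pq <- outer(px, py); m <- p > 0 & pq > 0
            -sum(p[m] * log(pq[m])) }
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0

  c(energy = energy, entropy = entropy, homogeneity = homogeneity,
    dissimilarity = dissimilarity, correlation = correlation,
    contrast = contrast, variance = variance, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    diff_variance = diff_variance, diff_entropy = diff_entropy,
    imc1 = imc1)
}
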