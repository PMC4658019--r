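#' Local binary pattern features
#'
#' Rotation-invariant uniform LBP at radius 3 with 24 circular sample
#' points, computed on the rescaled patch. Within an 8x8 ROI only the four
#' central voxels (0-based rows/cols 3..4) have the full radius-3 circle
#' inside the patch; each contributes one pattern. Neighbors are sampled
#' by bilinear interpolation; a bit is 1 where the neighbor is greater
#' than or equal to the center (ties count as 1, which makes the
#' constant-patch case deterministic). A pattern is uniform iff its
#' circular 0/1 sequence has at most two transitions; uniform patterns are
#' summarized by their set-bit count (0..24), all non-uniform patterns
#' share one bucket.
#'
#' The 12-bin histogram maps the 25 uniform codes onto 11 near-equal
#' contiguous ranges of set-bit counts (bin b covers counts
#' `floor((b-1) * 25/11) .. floor(b * 25/11) - 1`), with bin 12 holding
#' non-uniform patterns. The histogram is normalized to sum 1.
#'
#' Because 24 is divisible by 4, quarter-turn rotations of the patch map
#' sample points onto each other, so the features are invariant under
#' 90-degree rotation; thresholding against the center makes them
#' invariant under strictly increasing intensity transforms.
#'
#' @param patch An `roi_patch`.
#' @return Named numeric vector of length 12 summing to 1.
#' @export
compute_lbp_features <- function(patch) {
  x <- patch$rescaled
  counts <- numeric(12)
  for (r in 4:5) for (cc in 4:5) {        # 1-based centers (0-based 3..4)
    code <- lbp_code(x, r, cc, radius = 3, points = 24L)
    counts[code] <- counts[code] + 1
  }
  h <- counts / sum(counts)
  names(h) <- lbp_feature_names()
  h
}

# Bin index (1..12) for one center: uniform patterns binned by set-bit
# count, non-uniform in bin 12.
lbp_code <- function(x, r, cc, radius, points) {
  theta <- 2 * pi * (seq_len(points) - 1) / points
  nr <- r - radius * sin(theta)
  nc <- cc + radius * cos(theta)
  nb <- bilinear(x, nr, nc)
  bits <- as.integer(nb >= x[r, cc])
  trans <- sum(bits != c(bits[-1], bits[1]))
  if (trans <= 2) lbp_uniform_bin(sum(bits)) else 12L
}

lbp_uniform_bin <- function(nset) {
  # counts 0..24 partitioned into 11 contiguous near-equal ranges
  findInterval(nset, floor((0:11) * 25 / 11), rightmost.closed = FALSE)
}

bilinear <- function(x, r, cc) {
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  # clamp the upper corner for points landing exactly on the last row/col
  r1 <- pmin(r0 + 1, nrow(x)); c1 <- pmin(c0 + 1, ncol(x))
  x[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    x[cbind(r1, c0)] * fr * (1 - fc) +
    x[cbind(r0, c1)] * (1 - fr) * fc +
    x[cbind(r1, c1)] * fr * fc
}
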