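#' Discrete orthonormal Stockwell transform harmonics image
#'
#' Computes the unnormalized 2D discrete Fourier transform of the raw 8x8
#' patch and partitions the frequency plane into non-overlapping dyadic
#' sections per axis. For N = 8 the per-axis frequency sets are
#' `{0}, {1}, {-1}, {2,3}, {-2,-3}, {-4}` (the Nyquist frequency completes
#' coverage), carrying section orders 0, 1, -1, 2, -2, 3. Averaging the
#' Fourier amplitudes within each 2D section yields the 6x6 harmonics
#' image.
#'
#' With the unnormalized forward transform, Parseval's identity reads
#' `sum(|F|^2) = 64 * sum(x^2)`.
#'
#' @param patch An `roi_patch`.
#' @return List with `harmonics` (6x6 matrix of mean amplitudes) and
#'   `orders` (per-axis section orders).
#' @export
dost_harmonics <- function(patch) {
  f <- stats::fft(patch$raw)
  amp <- Mod(f)
  # FFT index k (0-based) -> signed frequency: 0..3 stay, 4..7 -> -4..-1
  freq <- c(0:3, -4:-1)
  sections <- list(0L, 1L, -1L, c(2L, 3L), c(-2L, -3L), -4L)
  orders <- c(0L, 1L, -1L, 2L, -2L, 3L)
  sec_of <- integer(8)
  for (s in seq_along(sections)) sec_of[freq %in% sections[[s]]] <- s
  h <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    h[a, b] <- mean(amp[sec_of == a, sec_of == b])
  }
  list(harmonics = h, orders = orders)
}

#' DOST texture features
#'
#' Reduces the harmonics image to 5 rotation-invariant features: the DC
#' section amplitude; the mean harmonics amplitude over sections at radial
#' order r = 1, 2, 3 where r = max(|order_x|, |order_y|); and the
#' normalized spectral entropy of the four band energies (squared band
#' amplitudes normalized to sum 1; entropy divided by log 4, defined as 0
#' when the total energy is 0). Radial banding by max absolute order makes
#' the features invariant under 90-degree patch rotation; a constant patch
#' has a DC-only spectrum so bands 1-3 vanish.
#'
#' @param patch An `roi_patch`.
#' @return Named numeric vector of length 5.
#' @export
compute_dost_features <- function(patch) {
  hh <- dost_harmonics(patch)
  r <- outer(abs(hh$orders), abs(hh$orders), pmax)
  f <- c(hh$harmonics[r == 0],
         mean(hh$harmonics[r == 1]),
         mean(hh$harmonics[r == 2]),
         mean(hh$harmonics[r == 3]))
  e <- f^2
  tot <- sum(e)
  sent <- if (tot > 0) {
    pr <- e[e > 0] / tot
    -sum(pr * log(pr)) / log(4)
  } else 0
  c(dc = f[1], band1 = f[2], band2 = f[3], band3 = f[4],
    spectral_entropy = sent)
}
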