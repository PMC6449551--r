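#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' FFT-based CWT with an analytic Morlet wavelet,
#' `psihat(w) = exp(-(s w - omega0)^2 / 2)` for `w > 0`, using amplitude
#' (L1-type) normalisation: a unit-amplitude sinusoid at a scale's centre
#' frequency yields coefficients of modulus ~1 at that scale, independent of
#' the scale. This keeps the per-scale mean-absolute-coefficient features
#' comparable across the 30 scales and places the scale-response maximum
#' exactly at the matching scale. Centre frequency of scale s is
#' `f = omega0 / (2 pi s)`, so scales are derived from the requested centre
#' frequencies.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param freq_hz Centre frequencies (Hz) of the analysis scales.
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return Complex matrix, `length(freq_hz)` rows x `length(x)` columns;
#'   row k is the coefficient series at `freq_hz[k]`.
#' @export
cwt_morlet <- function(x, fs, freq_hz, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  # zero-pad to at least twice the signal length so the longest wavelets
  # do not wrap around circularly
  npad <- 2^ceiling(log2(2 * n))
  xhat <- stats::fft(c(x, numeric(npad - n)))
  w <- 2 * pi * seq(0, npad - 1) / (npad * dt)
  w[w > pi / dt] <- w[w > pi / dt] - 2 * pi / dt  # signed angular freqs
  scales <- omega0 / (2 * pi * freq_hz)           # seconds
  out <- matrix(0i, length(freq_hz), n)
  pos <- w > 0
  for (k in seq_along(scales)) {
    s <- scales[k]
    daughter <- numeric(npad)
    # factor 2 restores unit modulus for a real unit-amplitude sinusoid
    daughter[pos] <- 2 * exp(-(s * w[pos] - omega0)^2 / 2)
    wt <- stats::fft(xhat * daughter, inverse = TRUE) / npad
    out[k, ] <- wt[seq_len(n)]
  }
  out
}
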