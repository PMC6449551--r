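#' Canonical 69-feature schema
#'
#' Every epoch yields exactly 69 named features: 9 from the time domain,
#' 23 from the frequency domain and 37 from the wavelet domain. The order
#' below is canonical and versioned; feature tables are written and validated
#' against it.
#'
#' Time (9): `mean`, `var`, `skew`, `kurt`, `peak`, `slope`, `auc`, `rms`,
#' `timepeak`. Frequency (23): Fourier magnitudes `F1`..`F15` (8 VLFO +
#' 7 LFO bins), then per-band mean (`mfvl`, `mfl`), variance (`varvl`,
#' `varl`), maximum energy (`maxvl`, `maxl`) and frequency of maximum energy
#' (`fmaxvl`, `fmaxl`). Wavelet (37): per-scale mean absolute coefficients
#' `W1`..`W30` (9 LFO + 21 VLFO scales), then per-band mean (`mwvl`, `mwl`),
#' variance (`vwvl`, `vwl`), wavelet power spectrum (`wpsvl`, `wpsl`) and the
#' absolute mean ratio `amr`.
#'
#' @param domain Optional, one of `"time"`, `"frequency"`, `"wavelet"` to
#'   return one domain's names only.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(domain = c("all", "time", "frequency", "wavelet")) {
  domain <- match.arg(domain)
  time_f <- c("mean", "var", "skew", "kurt", "peak", "slope", "auc", "rms",
              "timepeak")
  freq_f <- c(paste0("F", 1:15),
              "mfvl", "mfl", "varvl", "varl", "maxvl", "maxl",
              "fmaxvl", "fmaxl")
  wav_f <- c(paste0("W", 1:30),
             "mwvl", "mwl", "vwvl", "vwl", "wpsvl", "wpsl", "amr")
  switch(domain,
         all = c(time_f, freq_f, wav_f),
         time = time_f,
         frequency = freq_f,
         wavelet = wav_f)
}

#' Metadata columns preceding the features in a feature table
#' @noRd
feature_meta_cols <- function() c("subject", "trial", "channel", "label")

#' The 13-feature pain biomarker preset
#'
#' The named subset of the 69 features (in its canonical ranking order) that
#' serves as a compact candidate biomarker of thermal pain: one time-to-peak
#' and mean from the time domain, Fourier magnitudes and band variances from
#' the VLFO/LFO bands, and wavelet coefficients concentrated in the VLFO
#' band.
#'
#' @return Character vector of 13 canonical feature names, rank order.
#' @export
biomarker_features <- function() {
  c("timepeak", "F5", "W5", "W29", "varvl", "vwvl", "mean",
    "W11", "F11", "vwl", "W25", "F7", "W21")
}

#' Spectral grid for Fourier features
#'
#' The DFT grid used by [extract_freq()]: 15 bins at centre frequencies
#' `j * delta_f`, `j = 1..15`, with `delta_f = 1/epoch_len_s` (1/90 Hz by
#' default). Bins 1..8 form the very-low-frequency-oscillation (VLFO) group
#' and bins 9..15 the low-frequency-oscillation (LFO) group, honouring the
#' 8 + 7 band split (bin 8, 0.0889 Hz, is grouped with VLFO even though it
#' sits just above the nominal 0.08 Hz band edge).
#'
#' @param epoch_len_s Epoch length in seconds (default 90).
#' @return A list with `delta_f_hz`, `bins` (1..15), `freq_hz` (centre
#'   frequencies), and `band` (factor `"VLFO"`/`"LFO"` per bin).
#' @export
spectral_grid <- function(epoch_len_s = 90) {
  delta_f <- 1 / epoch_len_s
  bins <- 1:15
  structure(
    list(delta_f_hz = delta_f,
         bins = bins,
         freq_hz = bins * delta_f,
         band = factor(ifelse(bins <= 8, "VLFO", "LFO"),
                       levels = c("VLFO", "LFO")),
         epoch_len_s = epoch_len_s),
    class = "spectral_grid")
}

#' Wavelet scale grid for CWT features
#'
#' Thirty continuous-wavelet scales on a geometric frequency grid with 10
#' voices per octave: centre frequencies `f_k = f_top * 2^(-(k-1)/10)`,
#' `k = 1..30`, `f_top = 0.1492` Hz. Scales are indexed from high to low
#' frequency; scales 1..9 (above 0.08 Hz) form the LFO group and 10..30 the
#' VLFO group, giving the 9 + 21 band split. Adjacent scales differ in
#' frequency by a factor `2^(1/10)`.
#'
#' @param f_top_hz Highest centre frequency (default 0.1492 Hz).
#' @param n_scales Number of scales (default 30).
#' @param voices_per_octave Scales per frequency doubling (default 10).
#' @param omega0 Morlet mother-wavelet centre frequency parameter
#'   (default 6).
#' @return A list with `scales_idx`, `freq_hz`, `band`, and the Morlet
#'   parameter `omega0`.
#' @export
wavelet_grid <- function(f_top_hz = 0.1492, n_scales = 30,
                         voices_per_octave = 10, omega0 = 6) {
  k <- seq_len(n_scales)
  freq <- f_top_hz * 2^(-(k - 1) / voices_per_octave)
  structure(
    list(scales_idx = k,
         freq_hz = freq,
         band = factor(ifelse(freq >= 0.08, "LFO", "VLFO"),
                       levels = c("VLFO", "LFO")),
         f_top_hz = f_top_hz,
         voices_per_octave = voices_per_octave,
         omega0 = omega0),
    class = "wavelet_grid")
}
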