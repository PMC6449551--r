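#' Time-domain features of an epoch
#'
#' The nine descriptive statistics of the HbO activation curve: mean,
#' variance (N-1 denominator), skewness and kurtosis (1/(N-1) normalisation
#' over standardized deviations; kurtosis is raw, not excess), peak
#' amplitude, least-squares slope (per second, fitted with an intercept),
#' trapezoid area under the curve (dx = 1/fs), RMS, and time to the first
#' maximum in seconds.
#'
#' A zero-variance epoch yields skewness and kurtosis 0 by convention (never
#' NaN).
#'
#' @param epoch An `epoch` from [extract_epochs()], or any list with numeric
#'   `x` and `fs`.
#' @return Named numeric vector of length 9 (see [feature_names()]).
#' @export
extract_time <- function(epoch) {
  x <- epoch$x
  fs <- epoch$fs
  n <- length(x)
  if (n < 2) stop("epoch must have at least 2 samples", call. = FALSE)
  mu <- mean(x)
  v <- sum((x - mu)^2) / (n - 1)
  sdv <- sqrt(v)
  if (sdv > 0) {
    sk <- sum(((x - mu) / sdv)^3) / (n - 1)
    ku <- sum(((x - mu) / sdv)^4) / (n - 1)
  } else {
    sk <- 0
    ku <- 0
  }
  tsec <- (seq_len(n) - 1) / fs
  beta <- stats::cov(tsec, x) / stats::var(tsec)
  auc <- sum((x[-1] + x[-n]) / 2) / fs
  peak_idx <- which.max(x)[1]  # earliest maximum wins ties
  c(mean = mu, var = v, skew = sk, kurt = ku,
    peak = max(x), slope = beta, auc = auc,
    rms = sqrt(mean(x^2)), timepeak = (peak_idx - 1) / fs)
}

#' Frequency-domain features of an epoch
#'
#' DFT of the mean-removed epoch on the spectral grid: `F1..F15` are the
#' Fourier magnitudes `|F[j]|` at centre frequencies `j/epoch_len_s`; per
#' band (VLFO bins 1..8, LFO bins 9..15) the mean and variance of the
#' magnitudes, the maximum energy `|F|^2`, and the centre frequency (Hz) of
#' that maximum (lowest-frequency winner on ties).
#'
#' @inheritParams extract_time
#' @param grid A [spectral_grid()]; the epoch length must equal
#'   `grid$epoch_len_s * fs` (no silent re-gridding).
#' @return Named numeric vector of length 23.
#' @export
extract_freq <- function(epoch, grid = spectral_grid()) {
  x <- epoch$x
  n <- length(x)
  n_expected <- round(grid$epoch_len_s * epoch$fs)
  if (n != n_expected) {
    stop(sprintf("epoch length %d does not match the grid (%d samples)",
                 n, n_expected), call. = FALSE)
  }
  X <- stats::fft(x - mean(x))
  mag <- Mod(X[grid$bins + 1L])  # bin j -> fft index j+1
  names(mag) <- paste0("F", grid$bins)
  band_feats <- function(band) {
    sel <- grid$band == band
    m <- mag[sel]
    e <- m^2
    i <- which.max(e)[1]
    c(mean(m), stats::var(m), max(e), grid$freq_hz[sel][i])
  }
  vl <- band_feats("VLFO")
  lf <- band_feats("LFO")
  c(mag,
    mfvl = vl[1], mfl = lf[1], varvl = vl[2], varl = lf[2],
    maxvl = vl[3], maxl = lf[3], fmaxvl = vl[4], fmaxl = lf[4])
}

#' Wavelet-domain features of an epoch
#'
#' Morlet CWT at the 30 grid scales. `W1..W30` are the time-means of the
#' absolute coefficients per scale; per band (LFO scales 1..9, VLFO scales
#' 10..30) the mean of the per-scale values, the variance of all absolute
#' coefficients in the band, and the wavelet power spectrum
#' `sum(|W|^2)` over the band's scales and times; finally the absolute mean
#' ratio `amr = |mw(VLFO) - mw(LFO)|`.
#'
#' @inheritParams extract_time
#' @param grid A [wavelet_grid()].
#' @return Named numeric vector of length 37.
#' @export
extract_wavelet <- function(epoch, grid = wavelet_grid()) {
  x <- epoch$x
  if (!all(is.finite(x))) stop("epoch contains non-finite values",
                               call. = FALSE)
  W <- cwt_morlet(x, epoch$fs, grid$freq_hz, grid$omega0)
  A <- Mod(W)
  wbar <- rowMeans(A)
  names(wbar) <- paste0("W", grid$scales_idx)
  band_feats <- function(band) {
    sel <- grid$band == band
    coefs <- A[sel, , drop = FALSE]
    c(mean(wbar[sel]),
      if (length(coefs) > 1) stats::var(as.vector(coefs)) else 0,
      sum(coefs^2))
  }
  vl <- band_feats("VLFO")
  lf <- band_feats("LFO")
  c(wbar,
    mwvl = vl[1], mwl = lf[1], vwvl = vl[2], vwl = lf[2],
    wpsvl = vl[3], wpsl = lf[3], amr = abs(vl[1] - lf[1]))
}

#' Extract the full 69-feature table from a set of epochs
#'
#' One row per (trial, channel) epoch: metadata columns `subject`, `trial`,
#' `channel`, `label`, then the 69 features in canonical order.
#'
#' @param epochs List of epochs from [extract_epochs()] (possibly across
#'   recordings).
#' @param spectral Spectral grid (defaults match a 90-s epoch).
#' @param wavelet Wavelet scale grid.
#' @return A `data.frame` feature table with `4 + 69` columns.
#' @export
extract_all <- function(epochs, spectral = spectral_grid(),
                        wavelet = wavelet_grid()) {
  rows <- lapply(epochs, function(ep) {
    c(extract_time(ep), extract_freq(ep, spectral),
      extract_wavelet(ep, wavelet))
  })
  feat <- do.call(rbind, rows)
  stopifnot(identical(colnames(feat), feature_names()))
  if (!all(is.finite(feat))) stop("non-finite feature value produced",
                                  call. = FALSE)
  meta <- data.frame(
    subject = vapply(epochs, function(e) e$subject_id, character(1)),
    trial = vapply(epochs, function(e) as.integer(e$trial_id), integer(1)),
    channel = vapply(epochs, function(e) as.integer(e$channel), integer(1)),
    label = vapply(epochs, function(e) as.integer(e$label), integer(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feat))
}

#' Select the 13-feature biomarker subset
#'
#' Keeps the metadata columns and, in ranking order, the 13 canonical
#' biomarker features (see [biomarker_features()]).
#'
#' @param table A feature table from [extract_all()].
#' @param names_ Feature names to keep, in order (defaults to the biomarker
#'   preset). Unknown names raise a schema error.
#' @return The reduced feature table.
#' @export
biomarker_subset <- function(table, names_ = biomarker_features()) {
  unknown <- setdiff(names_, feature_names())
  if (length(unknown)) {
    stop("unknown feature name(s) in preset: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  table[, c(feature_meta_cols(), names_)]
}

#' Write / read a feature table as CSV
#'
#' Metadata columns first, then the 69 canonical feature columns; doubles
#' survive the round trip exactly. Reading validates the column set against
#' the canonical schema and names any missing or extra columns.
#'
#' @param table Feature table from [extract_all()].
#' @param path CSV path.
#' @return `read_feature_table()` returns the validated `data.frame`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  check_feature_schema(names(table))
  out <- table[, c(feature_meta_cols(), feature_names())]
  utils::write.csv(csv_full_precision(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path)
  check_feature_schema(names(tab))
  tab$subject <- as.character(tab$subject)
  tab
}

check_feature_schema <- function(cols) {
  expected <- c(feature_meta_cols(), feature_names())
  missing_cols <- setdiff(expected, cols)
  extra <- setdiff(cols, expected)
  if (length(missing_cols) || length(extra)) {
    stop(sprintf("feature table schema mismatch; missing: [%s]; extra: [%s]",
                 paste(missing_cols, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
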