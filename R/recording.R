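#' Construct an fNIRS recording
#'
#' A `recording` bundles one subject's multi-channel oxyhaemoglobin (HbO)
#' time series with its stimulus event table and sampling rate. Channels are
#' rows of `hbo`; samples are columns.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param hbo Numeric matrix, channels x samples, finite values
#'   (concentration units, e.g. mM.mm).
#' @param fs Sampling rate in Hz (the acquisition system here samples at 10).
#' @param events Data frame with columns `onset_s` (seconds from recording
#'   start), `label` (pain class code 1..4 for stimulus rows, NA for rest),
#'   and `kind` (`"stimulus"` or `"rest"`). Onsets must be strictly
#'   increasing.
#' @return An object of class `recording`.
#' @seealso [read_recording()], [extract_epochs()]
#' @export
recording <- function(subject_id, hbo, fs = 10, events = empty_events()) {
  if (!is.matrix(hbo) || !is.numeric(hbo)) {
    stop("`hbo` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (!all(is.finite(hbo))) {
    bad <- which(!is.finite(hbo), arr.ind = TRUE)[1, ]
    stop(sprintf("`hbo` contains a non-finite value at channel %d, sample %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  events <- validate_events(events)
  dur <- ncol(hbo) / fs
  if (any(events$onset_s >= dur)) {
    bad <- events$onset_s[events$onset_s >= dur]
    stop(sprintf("event onset(s) %s s lie at/beyond recording end (%.1f s)",
                 paste(bad, collapse = ", "), dur), call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), hbo = hbo, fs = fs,
         n_channels = nrow(hbo), events = events),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channels x %d samples @ %g Hz, %d stimulus events\n",
              x$subject_id, x$n_channels, ncol(x$hbo), x$fs,
              sum(x$events$kind == "stimulus")))
  invisible(x)
}

# render double columns with %.17g so text emission round-trips bit-exactly
csv_full_precision <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) ifelse(is.na(col), NA, sprintf("%.17g", col)) else col
  })
  df
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), label = integer(0), kind = character(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events) {
  req <- c("onset_s", "label", "kind")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- as.data.frame(events)[req]
  if (nrow(events)) {
    if (any(diff(events$onset_s) <= 0)) {
      i <- which(diff(events$onset_s) <= 0)[1] + 1L
      stop(sprintf("event onsets must be strictly increasing (row %d)", i),
           call. = FALSE)
    }
    stim <- events$kind == "stimulus"
    if (!all(events$kind %in% c("stimulus", "rest"))) {
      stop("event `kind` must be 'stimulus' or 'rest'", call. = FALSE)
    }
    lab <- events$label[stim]
    if (any(is.na(lab)) || !all(lab %in% 1:4)) {
      stop("stimulus rows must carry a pain class label in 1..4", call. = FALSE)
    }
  }
  events$label <- as.integer(events$label)
  events
}

#' Read / write a recording bundle
#'
#' A recording is stored as three sibling files sharing a path prefix:
#' `<prefix>_hbo.csv` (rows = samples, columns = channels, header = channel
#' names), `<prefix>_events.csv` (`onset_s,label,kind`), and
#' `<prefix>_meta.json` (`subject_id`, `fs`). All text is UTF-8 with '.' as
#' decimal separator; doubles survive the round trip exactly.
#'
#' @param path Path prefix of the bundle (no suffix).
#' @param rec A `recording` (for `write_recording`).
#' @return `read_recording()` returns a validated `recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path) {
  hbo_f <- paste0(path, "_hbo.csv")
  ev_f <- paste0(path, "_events.csv")
  meta_f <- paste0(path, "_meta.json")
  for (f in c(hbo_f, ev_f, meta_f)) {
    if (!file.exists(f)) stop("missing bundle file: ", f, call. = FALSE)
  }
  hbo_df <- utils::read.csv(hbo_f)
  if (!ncol(hbo_df)) stop("malformed header in ", hbo_f, call. = FALSE)
  if (!all(vapply(hbo_df, is.numeric, logical(1)))) {
    bad <- names(hbo_df)[!vapply(hbo_df, is.numeric, logical(1))][1]
    stop(sprintf("non-numeric samples in column '%s' of %s", bad, hbo_f),
         call. = FALSE)
  }
  hbo <- unname(t(as.matrix(hbo_df)))
  ev <- utils::read.csv(ev_f, colClasses = c(onset_s = "numeric",
                                             label = "integer",
                                             kind = "character"))
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  recording(meta$subject_id, hbo, fs = meta$fs, events = ev)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  hbo_df <- as.data.frame(t(rec$hbo))
  names(hbo_df) <- sprintf("ch%02d", seq_len(rec$n_channels))
  utils::write.csv(csv_full_precision(hbo_df), paste0(path, "_hbo.csv"),
                   row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.csv(csv_full_precision(rec$events),
                   paste0(path, "_events.csv"),
                   row.names = FALSE, quote = FALSE, na = "NA")
  jsonlite::write_json(list(subject_id = rec$subject_id, fs = rec$fs),
                       paste0(path, "_meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Cut stimulus-locked epochs from a recording
#'
#' One epoch per (stimulus event, channel). The epoch spans the half-open
#' window `[onset, onset + epoch_len_s)`; the start sample is
#' `floor(onset * fs)` (0-based). Epochs running past the end of the
#' recording are zero-padded to full length and flagged `padded = TRUE`.
#'
#' @param rec A `recording`.
#' @param epoch_len_s Epoch length in seconds (default 90, giving 900 samples
#'   at 10 Hz and a DFT resolution of 1/90 Hz).
#' @return A list of `epoch` objects, ordered by event then channel. Each
#'   epoch carries `subject_id`, `trial_id`, `channel`, `label`, `x`, `fs`,
#'   and `padded`.
#' @export
extract_epochs <- function(rec, epoch_len_s = 90) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0) {
    stop("`epoch_len_s` must be positive", call. = FALSE)
  }
  n <- round(epoch_len_s * rec$fs)
  stim <- rec$events[rec$events$kind == "stimulus", , drop = FALSE]
  out <- vector("list", nrow(stim) * rec$n_channels)
  k <- 0L
  n_total <- ncol(rec$hbo)
  for (i in seq_len(nrow(stim))) {
    start0 <- floor(stim$onset_s[i] * rec$fs)  # 0-based
    idx <- (start0 + 1L):min(start0 + n, n_total)
    pad <- length(idx) < n
    for (ch in seq_len(rec$n_channels)) {
      x <- as.numeric(rec$hbo[ch, idx])
      if (pad) x <- c(x, numeric(n - length(idx)))
      k <- k + 1L
      out[[k]] <- structure(
        list(subject_id = rec$subject_id, trial_id = i, channel = ch,
             label = stim$label[i], x = x, fs = rec$fs, padded = pad),
        class = "epoch")
    }
  }
  out
}
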