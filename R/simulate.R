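#' Simulation configuration
#'
#' Builds the configuration for the synthetic HbO recording generator. The
#' defaults emulate the study conditions the pipeline targets: 18 subjects,
#' 24 channels sampled at 10 Hz, a 60-s resting baseline, then 3 trials per
#' pain class in randomized order with 90-s analysis epochs separated by 30-s
#' rests.
#'
#' Classes differ along two axes. Intensity (low vs high pain) scales the
#' haemodynamic response amplitude; modality (cold vs heat) decides which
#' band carries extra narrowband oscillatory power — cold classes load the
#' VLFO band (0.01-0.08 Hz), heat classes the LFO band (0.08-0.15 Hz). All
#' channels additionally share systemic interference: cardiac (~1.25 Hz),
#' respiratory (~0.3 Hz), Mayer waves (~0.1 Hz), linear drift, white noise
#' and sparse motion-artifact transients.
#'
#' `*_power` values are the variance contributed by the narrowband component
#' (the sinusoid amplitude is `sqrt(2 * power)`), in squared concentration
#' units.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param n_channels Channels per recording (default 24).
#' @param n_trials_per_class Trials per pain class per subject (default 3).
#' @param fs Sampling rate, Hz (default 10).
#' @param epoch_len_s Stimulus epoch length, s (default 90).
#' @param rest_len_s Initial resting baseline, s (default 60).
#' @param isi_rest_s Rest between consecutive stimuli, s (default 30).
#' @param class_params Named list (LowCold/LowHeat/HighCold/HighHeat), each a
#'   list with `hrf_amplitude`, `hrf_peak_latency_s`, `vlfo_power`,
#'   `lfo_power`, `vlfo_peak_freq_hz`, `lfo_peak_freq_hz`.
#' @param noise_params List with `cardiac_freq_hz`, `cardiac_amp`,
#'   `resp_freq_hz`, `resp_amp`, `mayer_freq_hz`, `mayer_amp`, `drift_slope`
#'   (units/s), `white_sigma`, `artifact_rate_per_min`, `artifact_amp`.
#' @param subject_effect_sigma SD of the multiplicative subject random effect
#'   on activation amplitudes (default 0.1).
#' @param seed Master seed; together with the config it fully determines all
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 18, n_channels = 24,
                       n_trials_per_class = 3, fs = 10,
                       epoch_len_s = 90, rest_len_s = 60, isi_rest_s = 30,
                       class_params = default_class_params(),
                       noise_params = default_noise_params(),
                       subject_effect_sigma = 0.1, seed = 20190404) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_channels = as.integer(n_channels),
              n_trials_per_class = as.integer(n_trials_per_class),
              fs = fs, epoch_len_s = epoch_len_s, rest_len_s = rest_len_s,
              isi_rest_s = isi_rest_s,
              class_params = class_params, noise_params = noise_params,
              subject_effect_sigma = subject_effect_sigma,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_class_params <- function() {
  list(
    LowCold  = list(hrf_amplitude = 1.0, hrf_peak_latency_s = 6,
                    vlfo_power = 0.50, lfo_power = 0.05,
                    vlfo_peak_freq_hz = 1 / 22.5, lfo_peak_freq_hz = 0.122),
    LowHeat  = list(hrf_amplitude = 1.0, hrf_peak_latency_s = 6,
                    vlfo_power = 0.05, lfo_power = 0.50,
                    vlfo_peak_freq_hz = 1 / 22.5, lfo_peak_freq_hz = 0.122),
    HighCold = list(hrf_amplitude = 2.0, hrf_peak_latency_s = 6,
                    vlfo_power = 1.00, lfo_power = 0.05,
                    vlfo_peak_freq_hz = 1 / 22.5, lfo_peak_freq_hz = 0.122),
    HighHeat = list(hrf_amplitude = 2.0, hrf_peak_latency_s = 6,
                    vlfo_power = 0.05, lfo_power = 1.00,
                    vlfo_peak_freq_hz = 1 / 22.5, lfo_peak_freq_hz = 0.122))
}

default_noise_params <- function() {
  list(cardiac_freq_hz = 1.25, cardiac_amp = 0.4,
       resp_freq_hz = 0.3, resp_amp = 0.25,
       mayer_freq_hz = 0.1, mayer_amp = 0.15,
       drift_slope = 5e-4, white_sigma = 0.2,
       artifact_rate_per_min = 0.5, artifact_amp = 5)
}

validate_sim_config <- function(cfg) {
  np <- cfg$noise_params
  amps <- c(np$cardiac_amp, np$resp_amp, np$mayer_amp, np$white_sigma,
            np$artifact_amp, np$artifact_rate_per_min)
  if (any(amps < 0)) stop("noise amplitudes/rates must be >= 0", call. = FALSE)
  freqs <- c(np$cardiac_freq_hz, np$resp_freq_hz, np$mayer_freq_hz,
             vapply(cfg$class_params, function(p)
               c(p$vlfo_peak_freq_hz, p$lfo_peak_freq_hz), numeric(2)))
  if (any(freqs >= cfg$fs / 2)) {
    stop("all component frequencies must lie below the Nyquist rate",
         call. = FALSE)
  }
  for (p in cfg$class_params) {
    if (p$hrf_amplitude < 0 || p$vlfo_power < 0 || p$lfo_power < 0) {
      stop("class amplitudes/powers must be >= 0", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Canonical haemodynamic response kernel
#'
#' A double-gamma-shaped activation curve: a small initial dip, a single
#' positive peak at approximately `peak_latency_s`, then decay back to
#' baseline. The curve is scaled so its maximum equals `amplitude`.
#'
#' @param t_grid Non-negative, increasing time grid in seconds.
#' @param amplitude Peak value of the response (0 gives an all-zero kernel).
#' @param peak_latency_s Time of the positive peak, seconds (> 0).
#' @return Numeric vector, `length(t_grid)`.
#' @examples
#' h <- hrf_kernel(seq(0, 40, by = 0.1), 1, 6)
#' @export
hrf_kernel <- function(t_grid, amplitude, peak_latency_s) {
  if (peak_latency_s <= 0) stop("`peak_latency_s` must be > 0", call. = FALSE)
  if (any(diff(t_grid) <= 0) || any(t_grid < 0)) {
    stop("`t_grid` must be non-negative and increasing", call. = FALSE)
  }
  if (amplitude == 0) return(numeric(length(t_grid)))
  # unit-mode gamma bumps: g(t; p, a) peaks at t = p with value 1
  g <- function(t, p, a) ifelse(t <= 0, 0, (t / p)^a * exp(a * (1 - t / p)))
  main <- g(t_grid, peak_latency_s, 6)
  dip <- g(t_grid, peak_latency_s / 3, 2)
  undershoot <- g(t_grid, 2.5 * peak_latency_s, 8)
  h <- main - 0.2 * dip - 0.25 * undershoot
  amplitude * h / max(h)
}

# Deterministic 31-bit child seed from (master seed, subject index).
child_seed <- function(master, subject_index) {
  (abs(master) %% 100003L) * 20011L + subject_index * 7919L
}

#' Simulate one subject's recording
#'
#' Builds a recording as: a resting baseline, then `4 * n_trials_per_class`
#' stimuli in randomized order with inter-stimulus rests. Each channel is the
#' sum of (i) systemic signals shared across channels with random per-channel
#' gains (cardiac, respiration, Mayer wave, linear drift), (ii) trial-locked
#' class-dependent narrowband VLFO/LFO oscillations, (iii) the event-locked
#' haemodynamic response, (iv) white noise, and (v) Poisson-placed
#' step-plus-spike motion artifacts. Output is a pure function of
#' `(cfg, subject_index)`.
#'
#' @param cfg A [sim_config()].
#' @param subject_index Integer, 1-based subject number.
#' @return A list with elements `recording` (a [recording()]) and
#'   `ground_truth` (data frame of per-trial labels and latent activation
#'   amplitudes, plus artifact times as an attribute).
#' @export
simulate_subject <- function(cfg, subject_index) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, subject_index))
  fs <- cfg$fs
  n_trials <- 4L * cfg$n_trials_per_class
  trial_len_s <- cfg$epoch_len_s + cfg$isi_rest_s
  total_s <- cfg$rest_len_s + n_trials * trial_len_s
  n_samp <- round(total_s * fs)
  t <- (seq_len(n_samp) - 1) / fs
  nc <- cfg$n_channels

  # randomized class order, n_trials_per_class of each
  labels <- sample(rep(1:4, cfg$n_trials_per_class))
  onsets <- cfg$rest_len_s + (seq_len(n_trials) - 1) * trial_len_s

  np <- cfg$noise_params
  subj_gain <- max(0.1, 1 + stats::rnorm(1, 0, cfg$subject_effect_sigma))

  # shared systemic signals, random phases; channel-specific gains
  systemic <- rbind(
    np$cardiac_amp * sin(2 * pi * np$cardiac_freq_hz * t +
                           stats::runif(1, 0, 2 * pi)),
    np$resp_amp * sin(2 * pi * np$resp_freq_hz * t +
                        stats::runif(1, 0, 2 * pi)),
    np$mayer_amp * sin(2 * pi * np$mayer_freq_hz * t +
                         stats::runif(1, 0, 2 * pi)),
    np$drift_slope * t)
  gains <- matrix(1 + stats::rnorm(nc * 4, 0, 0.3), nc, 4)
  hbo <- gains %*% systemic

  # per-trial activation: HRF + narrowband class oscillations in the epoch
  ep_n <- round(cfg$epoch_len_s * fs)
  t_ep <- (seq_len(ep_n) - 1) / fs
  taper <- tukey_window(ep_n, 0.1)
  trial_amp <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    p <- cfg$class_params[[pain_class_name(labels[i])]]
    amp_i <- subj_gain * p$hrf_amplitude *
      max(0.1, 1 + stats::rnorm(1, 0, cfg$subject_effect_sigma))
    trial_amp[i] <- amp_i
    hrf <- hrf_kernel(t_ep, 1, p$hrf_peak_latency_s) * amp_i
    i0 <- floor(onsets[i] * fs)  # 0-based epoch start
    idx <- (i0 + 1L):(i0 + ep_n)
    a_v <- sqrt(2 * p$vlfo_power) * subj_gain
    a_l <- sqrt(2 * p$lfo_power) * subj_gain
    for (ch in seq_len(nc)) {
      osc <- a_v * sin(2 * pi * p$vlfo_peak_freq_hz * t_ep +
                         stats::runif(1, 0, 2 * pi)) +
        a_l * sin(2 * pi * p$lfo_peak_freq_hz * t_ep +
                    stats::runif(1, 0, 2 * pi))
      hbo[ch, idx] <- hbo[ch, idx] + hrf + osc * taper
    }
  }

  # white noise
  hbo <- hbo + matrix(stats::rnorm(nc * n_samp, 0, np$white_sigma), nc)

  # motion artifacts: Poisson-placed spike + step transients per channel
  n_art <- stats::rpois(1, np$artifact_rate_per_min * total_s / 60)
  art_t <- sort(stats::runif(n_art, 0, total_s))
  for (ta in art_t) {
    ch <- sample.int(nc, 1)
    j0 <- floor(ta * fs) + 1L
    spike_len <- min(round(fs), n_samp - j0 + 1L)
    if (spike_len < 1L) next
    shape <- exp(-(seq_len(spike_len) - 1) / (0.15 * fs))
    sgn <- sample(c(-1, 1), 1)
    hbo[ch, j0:(j0 + spike_len - 1L)] <-
      hbo[ch, j0:(j0 + spike_len - 1L)] + sgn * np$artifact_amp * shape
  }

  events <- rbind(
    data.frame(onset_s = 0, label = NA_integer_, kind = "rest",
               stringsAsFactors = FALSE),
    data.frame(onset_s = onsets, label = labels, kind = "stimulus",
               stringsAsFactors = FALSE))
  rec <- recording(sprintf("S%02d", subject_index), hbo, fs = fs,
                   events = events)
  gt <- data.frame(trial = seq_len(n_trials), label = labels,
                   onset_s = onsets, activation_amplitude = trial_amp)
  attr(gt, "artifact_times_s") <- art_t
  list(recording = rec, ground_truth = gt)
}

tukey_window <- function(n, alpha) {
  # tapered cosine window; keeps narrowband trial oscillations from
  # introducing hard onset/offset edges
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    i <- 0:edge
    ramp <- 0.5 * (1 + cos(pi * (2 * i / (alpha * (n - 1)) - 1)))
    w[i + 1] <- ramp
    w[n - i] <- ramp
  }
  w
}

#' Simulate a full multi-subject dataset
#'
#' @param cfg A [sim_config()]; `cfg$seed` plus the per-subject index fully
#'   determine every recording (child seeds are derived deterministically).
#' @return A list of `n_subjects` elements, each as returned by
#'   [simulate_subject()].
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(seq_len(cfg$n_subjects), function(i) simulate_subject(cfg, i))
}
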