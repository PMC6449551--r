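# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast simulation: 6 subjects, 4 channels, 2 trials/class
small_cfg <- function(seed = 101, ...) {
  sim_config(n_subjects = 6, n_channels = 4, n_trials_per_class = 2,
             seed = seed, ...)
}

# noise-free config: pure class structure, no systemic/white/artifact noise
quiet_noise <- function() {
  list(cardiac_freq_hz = 1.25, cardiac_amp = 0, resp_freq_hz = 0.3,
       resp_amp = 0, mayer_freq_hz = 0.1, mayer_amp = 0, drift_slope = 0,
       white_sigma = 0, artifact_rate_per_min = 0, artifact_amp = 0)
}

# feature table from the small simulation, preprocessed; built once
small_feature_table <- function() {
  cached("small_tab", function() {
    cfg <- small_cfg()
    sims <- simulate_dataset(cfg)
    eps <- unlist(lapply(sims, function(s) {
      rec <- preprocess_recording(s$recording, preprocess_config(),
                                  rest_len_s = cfg$rest_len_s)
      extract_epochs(rec, cfg$epoch_len_s)
    }), recursive = FALSE)
    extract_all(eps)
  })
}

# study-scale feature table (18 subjects x 24 channels); built once,
# shared by the protocol-level tests
default_feature_table <- function() {
  cached("default_tab", function() {
    cfg <- sim_config()
    sims <- simulate_dataset(cfg)
    eps <- unlist(lapply(sims, function(s) {
      rec <- preprocess_recording(s$recording, preprocess_config(),
                                  rest_len_s = cfg$rest_len_s)
      extract_epochs(rec, cfg$epoch_len_s)
    }), recursive = FALSE)
    extract_all(eps)
  })
}

make_epoch <- function(x, fs = 10) list(x = x, fs = fs)

# direct-summation oracle for the nine time-domain features
time_features_oracle <- function(x, fs) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / (n - 1)
  s <- sqrt(v)
  sk <- if (s > 0) sum(((x - mu) / s)^3) / (n - 1) else 0
  ku <- if (s > 0) sum(((x - mu) / s)^4) / (n - 1) else 0
  tt <- (seq_len(n) - 1) / fs
  tbar <- sum(tt) / n
  beta <- sum((tt - tbar) * (x - mu)) / sum((tt - tbar)^2)
  auc <- sum((x[-1] + x[-n]) / 2) / fs
  c(mean = mu, var = v, skew = sk, kurt = ku, peak = max(x), slope = beta,
    auc = auc, rms = sqrt(sum(x^2) / n), timepeak = (which.max(x) - 1) / fs)
}

# entropy-based re-implementation of the greedy joint-MI ranking, written
# against raw count tables (independent of the package's plug-in route)
jmi_oracle <- function(X, y, n_bins = 10) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  mi_oracle <- function(a, b) ent(a) + ent(b) - ent(paste(a, b))
  disc <- lapply(X, function(v) as.integer(discretize(v,
    discretization_config(n_bins))))
  p <- length(disc)
  mi1 <- vapply(disc, function(d) mi_oracle(d, y), numeric(1))
  sel <- which(mi1 == max(mi1))[1]
  rem <- setdiff(seq_len(p), sel)
  while (length(rem)) {
    j <- vapply(rem, function(f) {
      sum(vapply(sel, function(s)
        mi_oracle(paste(disc[[f]], disc[[s]]), y), numeric(1)))
    }, numeric(1))
    pick <- rem[which(j == max(j))[1]]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  names(X)[sel]
}
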