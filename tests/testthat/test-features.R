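test_that("the canonical schema has 69 features split 9/23/37 with the
           canonical band structure", {
  expect_length(feature_names(), 69)
  expect_length(feature_names("time"), 9)
  expect_length(feature_names("frequency"), 23)
  expect_length(feature_names("wavelet"), 37)
  sg <- spectral_grid()
  expect_identical(as.vector(table(sg$band)), c(8L, 7L))
  wg <- wavelet_grid()
  expect_identical(as.vector(table(wg$band)), c(21L, 9L))
  expect_true(all(diff(sg$freq_hz) > 0))
  expect_equal(wg$freq_hz[11], wg$f_top_hz / 2)  # one octave below the top
})

test_that("grids reproduce the canonical biomarker frequencies", {
  sg <- spectral_grid()
  wg <- wavelet_grid()
  expect_equal(round(sg$freq_hz[11], 3), 0.122)   # F11
  expect_equal(round(wg$freq_hz[5], 3), 0.113)    # W5
  expect_equal(round(wg$freq_hz[11], 4), 0.0746)  # W11
  expect_equal(round(wg$freq_hz[21], 4), 0.0373)  # W21
  expect_equal(round(wg$freq_hz[25], 4), 0.0283)  # W25
  expect_equal(round(wg$freq_hz[29], 4), 0.0214)  # W29
})

test_that("time features match closed forms on constant and ramp epochs", {
  ep_c <- make_epoch(rep(2, 900))
  f <- extract_time(ep_c)
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["var"]], 0)
  expect_equal(f[["skew"]], 0)   # zero-variance convention
  expect_equal(f[["kurt"]], 0)
  expect_equal(f[["peak"]], 2)
  expect_equal(f[["slope"]], 0)
  expect_equal(f[["auc"]], 2 * 89.9)
  expect_equal(f[["rms"]], 2)
  expect_equal(f[["timepeak"]], 0)
  ramp <- make_epoch((0:899) / 10)
  expect_equal(extract_time(ramp)[["slope"]], 1)  # units per second
})

test_that("time features equal the direct-summation oracle", {
  set.seed(42)
  for (rep_i in 1:5) {
    n <- sample(c(20, 50), 1)
    x <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
    got <- extract_time(make_epoch(x))
    want <- time_features_oracle(x, 10)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("an on-bin sinusoid lands exactly on its Fourier feature", {
  sg <- spectral_grid()
  A <- 3
  x <- A * sin(2 * pi * sg$freq_hz[5] * (0:899) / 10)
  f <- extract_freq(make_epoch(x), sg)
  expect_equal(f[["F5"]], A * 900 / 2, tolerance = 1e-6)
  others <- f[paste0("F", setdiff(1:15, 5))]
  expect_lt(max(others), 1e-6 * A * 900)
  expect_equal(f[["fmaxvl"]], 5 / 90)
  expect_equal(f[["maxvl"]], (A * 450)^2, tolerance = 1e-6)
  # constant epoch: mean removal kills every coefficient
  fc <- extract_freq(make_epoch(rep(7, 900)), sg)
  expect_lt(max(abs(fc[paste0("F", 1:15)])), 1e-9)
  expect_error(extract_freq(make_epoch(rnorm(500)), sg), "does not match")
})

test_that("CWT response peaks at the matching grid scale", {
  wg <- wavelet_grid()
  for (k in c(5, 11, 21, 29)) {
    x <- sin(2 * pi * wg$freq_hz[k] * (0:899) / 10)
    w <- extract_wavelet(make_epoch(x), wg)
    expect_equal(which.max(w[1:30]), k,
                 info = sprintf("scale %d", k), ignore_attr = TRUE)
  }
  z <- extract_wavelet(make_epoch(numeric(900)), wg)
  expect_identical(max(abs(z)), 0)
})

test_that("balanced band content gives a near-zero absolute mean ratio", {
  # one equal-amplitude sinusoid per scale, random phases; the window must
  # be long enough (1800 s) for the slowest scales to be spectrally
  # resolved, otherwise beating between unresolved neighbours dominates
  wg <- wavelet_grid()
  n <- 18000
  for (seed in 1:4) {
    set.seed(seed)
    x <- rowSums(vapply(seq_len(30), function(k)
      sin(2 * pi * wg$freq_hz[k] * (0:(n - 1)) / 10 + runif(1, 0, 2 * pi)),
      numeric(n)))
    w <- extract_wavelet(make_epoch(x), wg)
    expect_lt(w[["amr"]], 0.05 * max(w[["mwvl"]], w[["mwl"]]))
  }
})

test_that("extract_all emits the full canonical table with no bad values", {
  cfg <- small_cfg(seed = 23)
  sim <- simulate_subject(cfg, 1)
  eps <- extract_epochs(sim$recording, cfg$epoch_len_s)
  tab <- extract_all(eps)
  expect_equal(nrow(tab), 8 * cfg$n_channels)  # trials x channels
  expect_identical(names(tab), c("subject", "trial", "channel", "label",
                                 feature_names()))
  expect_true(all(vapply(tab[feature_names()],
                         function(v) all(is.finite(v)), logical(1))))
})

test_that("the biomarker preset selects 13 features in ranking order", {
  tab <- small_feature_table()
  sub <- biomarker_subset(tab)
  expect_identical(names(sub), c("subject", "trial", "channel", "label",
                                 biomarker_features()))
  expect_length(biomarker_features(), 13)
  expect_error(biomarker_subset(tab, c("timepeak", "F99")), "F99")
})

test_that("feature tables round-trip with a stable canonical header", {
  tab <- utils::head(small_feature_table(), 10)
  f <- file.path(withr::local_tempdir(), "feat.csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(back[feature_names()], tab[feature_names()],
               ignore_attr = TRUE)
  # golden header: metadata then the versioned 69 names
  expect_identical(readLines(f, n = 1),
                   paste(c("subject", "trial", "channel", "label",
                           feature_names()), collapse = ","))
  expect_error(write_feature_table(tab[, -10], f), "schema mismatch")
  bad <- tab
  names(bad)[10] <- "bogus"
  f2 <- file.path(withr::local_tempdir(), "bad.csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_feature_table(f2), "schema mismatch")
})
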