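---
title: "Recognising thermal pain states from fNIRS oxyhaemoglobin signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising thermal pain states from fNIRS oxyhaemoglobin signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
haemodynamics optically: oxyhaemoglobin (HbO) concentration changes over
a grid of scalp channels, here 24 channels sampled at 10 Hz. During a
quantitative-sensory-testing style thermal experiment, a subject receives
cold and heat stimuli at two intensities — threshold-level (low pain) and
tolerance-level (high pain) — giving four conditions:

| code | class    | modality | intensity |
|------|----------|----------|-----------|
| 1    | LowCold  | cold     | low       |
| 2    | LowHeat  | heat     | low       |
| 3    | HighCold | cold     | high      |
| 4    | HighHeat | heat     | high      |

The task is to recognise which condition produced a given stimulus-locked
HbO epoch. The package implements the full chain: simulation of realistic
recordings, preprocessing, extraction of 69 features per epoch in three
domains, filter-based feature ranking, and a subject-level classification
protocol. The task-related haemodynamic response lives in two canonical
bands: very-low-frequency oscillations (VLFO, 0.01–0.08 Hz) and
low-frequency oscillations (LFO, 0.08–0.15 Hz); cardiac (~1.25 Hz),
respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz) physiology and slow drift
are interference.

## Data model and epoching

A `recording` holds one subject's channels × samples HbO matrix, the
sampling rate, and an event table of stimulus onsets with class labels.
Epochs are cut per (stimulus, channel) over the half-open window
`[onset, onset + 90 s)`; the start sample is `floor(onset * fs)`
(0-based), stated once and used everywhere. Epochs that overrun the end of
a recording are zero-padded to full length and flagged rather than dropped,
so epoch counts stay deterministic (`n_stimuli * n_channels` exactly) and
downstream code can exclude padded epochs explicitly.

The 90-s default epoch is deliberate: it makes the DFT resolution
`1/90 Hz`, which is the spacing of the package's spectral feature grid
(below), so Fourier features fall on exact bins. It is configurable, but
the spectral grid must be rebuilt to match
(`spectral_grid(epoch_len_s = ...)`); `extract_freq()` refuses silently
mismatched lengths rather than re-gridding.

## The synthetic study

No public recordings accompany this analysis problem, so the
`synthetic_data` module is a first-class citizen: it generates the study
the rest of the package is validated on. `sim_config()` defaults describe
that study — 18 subjects, 24 channels, 10 Hz, a 60-s resting baseline,
then 3 trials per class in randomized order, each a 90-s analysis window
followed by a 30-s rest.

Each channel is a sum of:

* **Systemic interference**, shared across channels with random
  per-channel gains: cardiac (1.25 Hz), respiratory (0.3 Hz), Mayer wave
  (0.1 Hz) sinusoids, plus linear drift. Sharing across channels is what
  makes rest-referenced PCA removal meaningful.
* **The event-locked haemodynamic response**: a double-gamma-shaped
  kernel (`hrf_kernel()`) with a small initial dip, a peak at ~6 s, and a
  mild undershoot, scaled by the class's amplitude.
* **Class-dependent narrowband oscillations** inside each trial window:
  cold classes add power at 1/22.5 Hz ≈ 0.044 Hz (VLFO), heat classes at
  0.122 Hz (LFO). Intensity doubles both the response amplitude
  (1 → 2 concentration units) and the narrowband power (0.5 → 1.0
  units²), so all three feature domains carry discriminative signal.
* **White noise** (σ = 0.2) and **motion artifacts**: Poisson-placed
  (0.5/min) one-sided exponential transients of amplitude 5, an order of
  magnitude above the signal.

Subject heterogeneity is a multiplicative gain on activation amplitudes
(σ = 0.1). Effect sizes are free parameters of the simulation — no
empirical effect sizes are available to calibrate against — so accuracies
measured on this synthetic study characterise the pipeline, not any real
cohort. What the simulator does **not** emulate: deoxyhaemoglobin and
optical coupling physics, spatial channel topology, heavy-tailed or
autocorrelated physiological variability, habituation across trials, and
real inter-subject covariance structure. Passing tests therefore
demonstrate correctness and internal consistency of the pipeline, not
expected clinical performance.

Determinism: every subject's recording is a pure function of
`(config, subject_index)` via an arithmetically derived 31-bit child seed,
so datasets reproduce bit-identically and are generated fresh at test
time rather than stored.

## Preprocessing

The cleaning chain runs in a fixed order per channel — low-pass FIR,
wavelet de-noising — then rest-referenced PCA across channels.

**FIR low-pass, 0.16 Hz cut-off.** Two modes exist because the nominal
specification ("4th order") is physically weak at 10 Hz sampling: a 5-tap
FIR has such a shallow roll-off that the cardiac line passes nearly
untouched. `fir_mode = "order4"` implements that literal filter;
`fir_mode = "effective"` (the default) designs a Hamming-window
linear-phase FIR with ~`3 * fs / cutoff` (≈ 189) taps, attenuating
1.25 Hz by more than 26 dB while passing 0.05 Hz within 1 %. Both are
applied with group-delay compensation (shift by `(taps-1)/2`, reflection
padding), because event-locked features must not be time-shifted. Taps are
renormalised to exact unit DC gain.

**Wavelet de-noising.** A 5-level discrete wavelet transform with the
symlet-4 filter bank (periodic boundary, implemented in the package since
no suitable wavelet package is available; validated by perfect
reconstruction and Parseval energy preservation). Within each detail
level, coefficients further than 1.5 interquartile ranges from the level
median are zeroed — the large sparse coefficients that motion transients
produce — and the signal is reconstructed. At 10 Hz with 5 levels the
detail bands cover ~0.16–5 Hz, above the haemodynamic bands, so smooth
VLFO/LFO content passes essentially unchanged while a 10-σ spike loses
over 80 % of its amplitude.

**Rest-referenced PCA.** Principal axes are fitted per subject on the
resting baseline (channels as variables, mean-centred); the smallest
leading set of components reaching 80 % of resting variance is projected
out of the stimulus-period data. A cumulative-variance threshold is used
rather than a fixed component count because the interference rank varies
between subjects; the number removed is reported. Setting the threshold
above 1 disables the step. Per-subject fitting is an interpretation
choice: resting data exist per subject, and systemic physiology is
subject-specific.

## The 69-feature schema

Features are computed per epoch and concatenated in a fixed, versioned
order (`feature_names()`): 9 time + 23 frequency + 37 wavelet features.

**Time (9):** mean, variance (N−1), skewness and kurtosis (1/(N−1)
normalisation of standardized deviations; kurtosis is raw, not excess;
both defined as 0 for zero-variance epochs rather than NaN), peak,
least-squares slope per second (fitted with an intercept so a baseline
offset cannot bias it), trapezoid area under the curve (dx = 1/fs), RMS,
and time to the first maximum (earliest-winner tie-break).

**Frequency (23):** the DFT of the mean-removed epoch (mean removal
prevents DC leakage into bin 1) evaluated at the 15 grid bins
`j/90 Hz, j = 1..15`. Bins 1–8 form the VLFO group and 9–15 the LFO
group; bin 8 (0.0889 Hz) is grouped with VLFO to keep the 8 + 7 split
even though it sits just above the nominal band edge. Features are the 15
magnitudes |F[j]|, then per band: mean and variance of the magnitudes,
maximum energy |F|², and the frequency of that maximum
(lowest-frequency tie-break). Magnitudes rather than complex values are
used throughout because band variances of complex coefficients are not
well-defined scalars; energy is their square.

**Wavelet (37):** a complex Morlet CWT (centre-frequency parameter
ω₀ = 6) evaluated at 30 scales on a geometric grid with 10 voices per
octave topping at 0.1492 Hz, so scale k has centre frequency
`0.1492 * 2^(-(k-1)/10)` Hz — e.g. W5 at 0.113 Hz, W11 at 0.0746 Hz, W21
at 0.0373 Hz, W29 at 0.0214 Hz. Scales 1–9 (≥ 0.08 Hz) are the LFO group
and 10–30 the VLFO group. Per scale, the feature is the time-mean of the
coefficient modulus; per band, the mean of those per-scale values, the
variance of all moduli, and the total power Σ|W|²; finally the absolute
mean ratio |μ(VLFO) − μ(LFO)|.

The CWT uses **amplitude (L1-type) normalisation**: a unit sinusoid at a
scale's centre frequency produces coefficients of modulus ~1 at that
scale regardless of scale. Under the common 1/√S (L2) convention the
per-scale means grow like √scale for equal-amplitude content, which makes
cross-scale means incomparable and biases the scale-response maximum; the
amplitude convention makes the 30 per-scale features directly
interpretable as band amplitudes and places the response maximum exactly
at the matching scale. The transform is FFT-based with zero-padding to at
least twice the signal length so the longest wavelets never wrap
circularly. A 13-feature biomarker preset (`biomarker_features()`)
selects, in rank order, the compact cross-domain subset the pipeline is
designed around.

## Feature ranking

All three criteria are filter methods computed on discretized features.
Discretization is equal-frequency with 10 bins by default (robust to the
heavy-tailed spectral features); when a feature has at most 10 distinct
values each value keeps its own bin, so label-like features retain their
full information. During evaluation, bin edges are fitted on training
subjects only and re-applied to held-out data.

* **IG** — mutual information (bits, plug-in estimator) between the
  binned feature and the class label.
* **χ²** — Pearson chi-squared statistic of the bins × classes table, no
  continuity correction.
* **JMI** — greedy forward ranking: the first feature maximizes I(f; Y);
  each later pick maximizes `J(f) = Σ_{s selected} I((f,s); Y)` over joint
  symbols of the candidate and each already-selected feature. This is the
  standard accumulation form of the criterion; it demotes redundant
  duplicates in favour of complementary features. The greedy objective is
  accumulated incrementally (the sum grows by one term per step), making
  the full 69-feature ranking run in seconds.

All rankings are deterministic, invariant to row order, and break ties by
canonical feature order so ranked-subset curves are reproducible.

## Evaluation protocol

Samples are (trial, channel) rows; all splitting is at the **subject**
level, because rows from one subject (same trial seen by 24 channels) are
strongly correlated and row-level splits would leak. Subjects are split
13 training / 5 validation. Hyperparameters are chosen by
leave-one-subject-out cross-validation over the 13 training subjects (13
folds); each fold z-scores features with fold-training statistics only.
Classifiers: LDA; K-NN (Euclidean, K = 1..20); and one-vs-one SVMs —
linear, Gaussian (RBF) and cubic polynomial — with C ∈ {0.1, 1, 10, 100}
and RBF γ ∈ {0.001, 0.01, 0.1, 1}. Hyperparameter ties resolve to the
simplest model (smallest K, then C, then γ). The chosen model is refitted
on all training rows and scored per validation subject as correct/total
over that subject's rows; reported accuracy is the mean of per-subject
accuracies, in percent. `accuracy_curve()` repeats the whole procedure for
each top-m ranked subset.

Numerical choices: SVMs run with convergence tolerance 0.01 (rather than
libsvm's 0.001) and a 200 MB kernel cache; on these data the looser
tolerance changes accuracies by well under one point while roughly
halving fit time. K-NN vote ties are broken under a fixed seed so the
whole pipeline is bit-reproducible.

## Problem sizes and runtime

The test suite validates most operations on small constructed inputs and
runs the full subject-level protocol on the default 18-subject study
(5184 epochs × 69 features). For that protocol check the RBF grid is
restricted to the six combinations around the operating point
(C ∈ {1, 10, 100}, γ ∈ {0.01, 0.1}) and the curve is evaluated at
m ∈ {13, 25, 69}, which keeps the check within a few minutes;
`scripts/acceptance.R` runs the same protocol with the full 16-point grid.
Pipeline determinism is exercised on a 4-subject, 3-channel
configuration.

## Known limitations

* Accuracies reflect the synthetic study's chosen effect sizes; they are
  not estimates of real-cohort performance.
* The wavelet de-noising IQR rule assumes artifacts are sparse; dense
  artifacts shift the level medians and reduce removal.
* PCA removal assumes systemic interference dominates rest; strong
  resting-state neural activity would be partially removed with it.
* Short-separation-channel regression and auxiliary physiological
  regressors are out of scope.
* HbR signals, optical-density conversion and probe geometry are not
  modelled; channel count is metadata only.
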