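Package: painfnirs
Title: Pain-State Classification from fNIRS Oxyhaemoglobin Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising thermal pain states
    (cold/heat at low/high intensity) from multi-channel functional
    near-infrared spectroscopy (fNIRS) oxyhaemoglobin recordings. Provides a
    physiologically structured simulator of 24-channel HbO recordings
    (haemodynamic responses, very-low and low frequency oscillations, cardiac,
    respiratory and Mayer-wave interference, drift and motion artifacts), a
    three-step preprocessing chain (linear-phase FIR low-pass filtering,
    wavelet de-noising of motion artifacts, rest-referenced PCA removal of
    systemic components), extraction of 69 named features per stimulus epoch
    in the time, frequency and wavelet domains, filter-based feature ranking
    by information gain, joint mutual information and chi-squared criteria,
    and subject-level evaluation with leave-one-subject-out cross-validated
    LDA, K-NN and SVM classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
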