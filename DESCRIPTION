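Package: fcghs
Title: Template-Matching Localization of Heart Sounds in Forcecardiography Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes first (S1) and second (S2) heart sounds, and whole
    S1-S2 heartbeat pairs, in forcecardiography (FCG) force-sensor recordings
    by normalized cross-correlation template matching. Provides the full
    processing chain: Savitzky-Golay respiratory baseline extraction,
    zero-phase Butterworth band-pass filtering of the heart-sound component,
    Pan-Tompkins R-peak detection on a concurrent ECG reference, template
    selection and NCC peak localization, true/false/missed event bookkeeping
    with sensitivity and positive predictive value, inter-beat interval
    agreement analysis (Passing-Bablok regression with cusum linearity test,
    Pearson correlation, Bland-Altman limits of agreement), and a heart rate
    variability index set spanning time-domain, frequency-domain (Welch
    spectrum with smoothness-priors detrending) and non-linear measures
    (Poincare, approximate and sample entropy, detrended fluctuation
    analysis). A seeded synthetic-signal generator emulating quasi-periodic
    S1/S2 wavelets, respiratory modulation and a concurrent ECG supports
    end-to-end validation with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
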