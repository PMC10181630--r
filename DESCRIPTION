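Package: hrvcoherence
Title: Cardiac Coherence Quantification from RR Intervals and Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cardiac coherence achieved during resonance frequency
    breathing (paced at 0.1 Hz) from beat-to-beat RR-interval series and
    chest-belt respiration waveforms. Implements ectopic-beat detection and
    correction, 4 Hz cubic-spline tachogram resampling, smoothness-priors
    detrending with a second-difference roughness penalty, single-segment
    windowed power spectral density estimation with dominant-peak analytics
    (location, height, mid-peak-height width), the RMSError of oscillation
    cycle durations against the 10-s resonance target, and the P0.1 index
    measuring how spectral power concentrates at the guided frequency.
    Includes a seeded synthetic-physiology generator (respiratory sinus
    arrhythmia, Mayer waves, tracking jitter, ectopic beats), an emulation of
    a haptic breathing-guidance device's heart-rate smoothness rule, and
    group-level statistics (Tukey outlier correction, one-way ANOVA, Holm
    post hoc tests, JZS Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    car,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
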