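Package: hrvrmc
Title: Refined Matrix Completion for Heart Rate Variability Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates missing or artefact-corrupted regions of heart rate
    variability (HRV) power spectra by exploiting the low-rank structure of
    stacked per-segment spectra. Provides the full RR-interval pipeline
    (outlier handling, dual-detector signal quality gating, uniform
    resampling, Butterworth band-pass, Welch periodograms), parametric
    Gaussian modelling of the LF (Mayer wave) and HF (respiratory sinus
    arrhythmia) bands, an interest-zone matrix approximation solver driven
    by bisection on a nuclear-norm bound, a refined completion method that
    restricts the solver to segments selected by modelled-spectrum
    correlation, a singular value thresholding baseline, and a seeded
    synthetic-data generator for desk-scale evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
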