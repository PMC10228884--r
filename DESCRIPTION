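Package: voicebias
Title: Device Bias in Voice Analytics: Measurement, Simulation, and Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify and correct systematic biases that
    consumer-grade audio-recording devices introduce into two fundamental
    vocal measures, fundamental frequency (f0) and amplitude. Provides a
    self-contained f0/intensity extractor for WAV audio (normalized
    autocorrelation with parabolic peak interpolation), a calibrated
    generative model of a nested within-subjects device study, from-scratch
    repeated-measures and mixed-design ANOVA with Tukey HSD contrasts and
    partial eta squared, a device-mixture simulation quantifying attenuation
    of emotion effect sizes when high-proximity microphones are oversampled,
    device-wise emotion and sex classification under subject-wise
    cross-validation, and a baseline-calibrated bias-correction procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
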