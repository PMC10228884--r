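# voicebias

Does the microphone change the science? `voicebias` is an R package for
studying — and correcting — the systematic biases that consumer-grade
audio-recording devices introduce into the two workhorse vocal measures,
fundamental frequency (f0, pitch) and amplitude (loudness). It is aimed at
researchers who analyze crowdsourced or multi-device voice recordings
(emotion research, voice-based screening, speaker profiling) and need to
know how much of a group difference is speaker and how much is hardware.

The package implements, as tested and reusable functions:

* **Feature extraction** from WAV audio: framewise normalized-
  autocorrelation pitch tracking with parabolic peak interpolation,
  Hann-weighted intensity in dB re 2·10⁻⁵, and local jitter/shimmer from
  marked pitch periods (`read_wav()`, `f0_contour()`,
  `intensity_contour()`, `extract_features()`).
* **A calibrated generative model** of a nested within-subjects device
  study — 30 participants × 5 devices (studio baseline, lavalier, headset,
  smartphone, laptop) × 3 emotions × 2 phrases × 2 headset conditions =
  1,800 recordings — with device/emotion/sex cell means and per-device
  dispersions (`generate_design()`, `sample_features()`,
  `default_effect_model()`, `synth_vowel()`).
* **Repeated-measures inference** written from first principles: one-way
  RM-ANOVA (`SS_cond = n Σ (ȳⱼ − ȳ)²` etc., `F = MS_cond/MS_err` on
  `(k−1, (n−1)(k−1))` df), balanced mixed designs with up to two within
  factors, Tukey HSD contrasts via the studentized range
  (`p = P(Q_{k,df} ≥ |t|√2)`), partial η², Cohen's d, and the
  Farrar–Glauber collinearity χ² (`rm_anova_oneway()`, `mixed_anova()`,
  `tukey_contrasts()`, `analyze_devices()`).
* **A device-mixture experiment** (`run_proportion_sim()`): vary the share
  of high-proximity lavalier recordings in synthetic samples of 480
  participants and measure how the detectable emotion effect on amplitude
  attenuates (one-way ANOVA on 1,440 pooled observations, `df = (2, 1437)`,
  average |d| over the three emotion contrasts).
* **Device-wise prediction and correction**: emotion (random forest) and
  sex (logit) classification under five-fold subject-wise
  cross-validation, and a baseline-calibrated bias correction mapping
  high-proximity features onto the studio baseline
  (`classify_emotion()`, `classify_sex()`, `fit_correction()`).

## Worked example

```r
library(voicebias)

design   <- generate_design(n_participants = 30, seed = 20260924)
features <- sample_features(design, default_effect_model(), seed = 20260925)
nrow(features)
#> [1] 1800

sort(tapply(features$mean_amp_db, features$device, mean), decreasing = TRUE)
#>   lavalier    headset   baseline smartphone     laptop
#>      63.58      60.18      57.95      53.03      47.00

analyze_devices(features, "mean_amp_db")
#> Device-bias analysis of mean_amp_db
#> condition: F(4, 116) = 518.26, p = 5.64e-73, partial eta^2 = 0.95
#>   device x sex: F(4, 112) = 14.08, p = 2.43e-09
#>   device x emotion: F(8, 232) = 2.15, p = 0.0323
```

The chest-worn lavalier inflates captured amplitude by ~6 dB over the
studio baseline and ~17 dB over the laptop; the device "effect" dwarfs any
speaker effect (partial η² = 0.95 here). That inflation has substantive
consequences — oversample the inflating device and the emotion effect
shrinks:

```r
sim <- run_proportion_sim(default_effect_model(), n_participants = 480,
                          proportions = c(0, 0.5, 1), n_seeds = 20,
                          base_seed = 42)
sim
#> Device-mixture simulation: 480 participants, 20 seeds
#>   proportion mean_neutral mean_happy mean_sad      F avg_d
#> 1        0.0       53.954     56.323   52.393 42.569 0.392
#> 2        0.5       58.717     60.401   57.477 16.010 0.240
#> 3        1.0       63.576     64.607   62.688 10.593 0.189
```

With no lavalier data the sad/happy groups differ by ~3.9 dB (medium
average effect, d ≈ 0.39); with lavalier-only data the same underlying
emotion manipulation yields d ≈ 0.19 and a barely significant F. The mean
columns follow the mixture identity
`π·μ_lavalier(e) + (1−π)·mean_other(μ(e))`.

The workflow drivers under `analysis/` run the complete study in order —
`01_simulate_study.R` (design + feature table), `02_device_bias.R`
(ANOVAs, Tukey contrasts, correlograms), `03_proportion_sim.R`,
`04_classification.R`, `05_bias_correction.R` — writing their tables under
`results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

## Layout

```
R/                  package code (extraction, generator, ANOVA, simulation,
                    classification, correction, pipeline)
analysis/           numbered workflow drivers writing results/
scripts/acceptance.R  headline-number reproduction
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, calibration, design choices)
```
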