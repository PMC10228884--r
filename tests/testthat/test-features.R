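test_that("pitch of a pure tone is recovered within 2 Hz and noise is unvoiced", {
  clip <- make_sine(220, amp = 0.1)
  f0c <- f0_contour(clip)
  expect_gt(mean(f0c$voiced), 0.95)
  expect_lt(max(abs(f0c$f0[f0c$voiced] - 220)), 2)

  noise <- audio_clip(withr::with_seed(7, stats::rnorm(44100, sd = 0.1)), 44100)
  expect_gte(mean(!f0_contour(noise)$voiced), 0.9)
})

test_that("sawtooth pitch matches an independent zero-crossing oracle within 1%", {
  rate <- 44100
  t <- seq.int(0L, rate - 1L) / rate
  saw <- audio_clip(0.2 * (2 * ((t * 120) %% 1) - 1), rate)
  # oracle: average period from upward zero crossings of the raw waveform
  x <- saw$samples
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  oracle_f0 <- rate / mean(diff(up))
  est <- f0_contour(saw)
  est_f0 <- mean(est$f0[est$voiced])
  expect_lt(abs(est_f0 - oracle_f0) / oracle_f0, 0.01)
  expect_lt(abs(est_f0 - 120) / 120, 0.01)
})

test_that("intensity follows the closed form and the dB shift law", {
  clip <- make_sine(220, amp = 0.1)
  ic <- intensity_contour(clip)
  expected <- 20 * log10((0.1 / sqrt(2)) / 2e-5)
  expect_lt(max(abs(ic$intensity_db - expected)), 0.05)

  doubled <- audio_clip(2 * clip$samples, clip$rate)
  shift <- intensity_contour(doubled)$intensity_db - ic$intensity_db
  expect_true(all(abs(shift - 20 * log10(2)) < 1e-9))

  # arbitrary scaling: dB shift law and pitch invariance
  scaled <- audio_clip(0.37 * clip$samples, clip$rate)
  expect_true(all(abs(
    intensity_contour(scaled)$intensity_db - ic$intensity_db -
      20 * log10(0.37)) < 1e-6))
  f1 <- f0_contour(clip); f2 <- f0_contour(scaled)
  expect_identical(f1$voiced, f2$voiced)
  expect_equal(f1$f0, f2$f0, tolerance = 1e-9)
})

test_that("all-zero frames are flagged silent, not errors", {
  x <- c(numeric(4410), 0.1 * sin(2 * pi * 200 * (0:8819) / 44100))
  ic <- intensity_contour(audio_clip(x, 44100))
  expect_true(any(ic$silent))
  expect_true(all(is.infinite(ic$intensity_db[ic$silent])))
  expect_error(f0_contour(audio_clip(numeric(100), 44100)),
               "insufficient signal")
})

test_that("a steady synthetic vowel has near-zero perturbation measures", {
  clip <- synth_vowel(150, rms = 0.05, duration = 0.8)
  vf <- extract_features(clip)
  expect_lt(abs(vf$mean_f0_hz - 150), 1.5)
  expect_lt(vf$sd_f0_hz, 1)
  expect_lt(vf$jitter_local, 0.003)
  expect_lt(vf$shimmer_local, 0.02)
  expect_lt(abs(vf$mean_amp_db - 20 * log10(0.05 / 2e-5)), 0.3)
})

test_that("alternating pitch periods give the closed-form local jitter", {
  # cycles of cos() peak exactly at the cycle boundaries, so measured
  # peak-to-peak intervals equal the constructed periods T(1 +/- eps);
  # mean |successive difference| / mean period = 2 eps
  rate <- 44100; t0 <- 1 / 150; eps <- 0.01
  periods <- rep(t0 * c(1 + eps, 1 - eps), 60)
  x <- unlist(lapply(periods, function(tp) {
    n <- round(tp * rate)
    cos(2 * pi * seq.int(0L, n - 1L) / n)
  }))
  clip <- audio_clip(0.1 * x, rate)
  vf <- suppressWarnings(extract_features(clip))
  expect_equal(vf$jitter_local, 2 * eps, tolerance = 0.15)
})

test_that("recordings with no voiced frames yield missing f0 with a warning", {
  noise <- audio_clip(withr::with_seed(3, stats::rnorm(22050, sd = 0.05)), 44100)
  expect_warning(vf <- extract_features(noise), "no voiced frames")
  expect_true(is.na(vf$mean_f0_hz))
  expect_identical(vf$n_voiced_frames, 0L)
  expect_false(is.na(vf$mean_amp_db))
})

test_that("synthetic vowels round-trip through the extractor across the speaking range", {
  for (f0 in c(100, 150, 200, 250)) {
    clip <- synth_vowel(f0, rms = 0.05, duration = 0.6, seed = f0)
    vf <- extract_features(clip)
    expect_lt(abs(vf$mean_f0_hz - f0) / f0, 0.01)
    expect_lt(abs(vf$mean_amp_db - 67.96), 0.3)
  }
})

test_that("vowel synthesis validates its parameters", {
  expect_error(synth_vowel(5000, 0.05, n_harmonics = 5), "aliasing")
  expect_error(synth_vowel(150, 0.9), "rms")
})
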