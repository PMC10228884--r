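# Shared fixtures: calibrations and small synthetic tables built in code.

# Default calibration with all emotion contrasts removed (every device keeps
# its overall mean for every emotion); f0 likewise flattened across emotions.
null_emotion_model <- function(...) {
  m <- default_effect_model()
  amp <- m$amp_mean
  amp[] <- rowMeans(amp)[row(amp)]
  f0 <- m$f0_mean
  for (s in dimnames(f0)[[3]])
    f0[, , s] <- rowMeans(f0[, , s])[row(f0[, , s])]
  default_effect_model(amp_mean = amp, f0_mean = f0, ...)
}

# Calibration whose sexes share every f0 cell and carry no amplitude offsets.
sexless_model <- function() {
  m <- default_effect_model()
  f0 <- m$f0_mean
  pooled <- (f0[, , "female"] + f0[, , "male"]) / 2
  f0[, , "female"] <- pooled
  f0[, , "male"] <- pooled
  off <- m$amp_sex_offset
  off[] <- 0
  default_effect_model(f0_mean = f0, amp_sex_offset = off)
}

make_table <- function(n_participants = 30L, seed = 1L,
                       model = default_effect_model()) {
  sample_features(generate_design(n_participants, seed), model, seed + 1L)
}

# Paired high-proximity/reference features with a configurable mapping.
make_paired <- function(n_participants = 24L, reps = 12L, seed = 1L,
                        transform = function(amp) amp - 6.01,
                        noise_sd = 0, f0_shift = -10) {
  withr::with_seed(seed, {
    ids <- rep(sprintf("P%02d", seq_len(n_participants)), each = reps)
    amp_high <- stats::rnorm(length(ids), 63.7, 6) +
      rep(stats::rnorm(n_participants, 0, 2), each = reps)
    f0_high <- stats::rnorm(length(ids), 170, 30)
    data.frame(participant_id = ids, device = "lavalier",
               amp_high = amp_high, f0_high = f0_high,
               amp_ref = transform(amp_high) +
                 stats::rnorm(length(ids), 0, noise_sd),
               f0_ref = f0_high + f0_shift +
                 stats::rnorm(length(ids), 0, noise_sd))
  })
}

# Monte-Carlo Bayes accuracy of sex given a device's per-recording (f0,
# amplitude) under a calibration: the oracle the logit model is held to.
bayes_sex_rate <- function(m, device, n = 2e5, seed = 77) {
  sd_f0 <- sqrt(m$sigma_f0_within[[device]]^2 + m$sigma_f0_participant^2)
  sd_amp <- sqrt(m$sigma_amp_within[[device]]^2 + m$sigma_amp_participant^2)
  lik <- function(f0, amp, s) {
    rowMeans(vapply(m$emotions, function(e)
      stats::dnorm(f0, m$f0_mean[device, e, s], sd_f0) *
        stats::dnorm(amp, m$amp_mean[device, e] +
                       m$amp_sex_offset[device, s], sd_amp),
      numeric(length(f0))))
  }
  withr::with_seed(seed, {
    sex <- rep(m$sexes, each = n / 2)
    emo <- sample(m$emotions, n, replace = TRUE)
    f0 <- stats::rnorm(n, m$f0_mean[cbind(device, emo, sex)], sd_f0)
    amp <- stats::rnorm(n, m$amp_mean[cbind(device, emo)] +
                          m$amp_sex_offset[cbind(device, sex)], sd_amp)
    pred <- ifelse(lik(f0, amp, "female") > lik(f0, amp, "male"),
                   "female", "male")
    mean(pred == sex)
  })
}

# Pure tone helper for extractor tests.
make_sine <- function(freq, amp = 0.1, duration = 1, rate = 44100) {
  t <- seq.int(0L, round(duration * rate) - 1L) / rate
  audio_clip(amp * sin(2 * pi * freq * t), rate)
}
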