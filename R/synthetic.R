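DEVICES <- c("baseline", "lavalier", "headset", "smartphone", "laptop")
EMOTIONS <- c("neutral", "happy", "sad")
SEXES <- c("female", "male")
PHRASES <- c("bar", "beer")
HEADSET_WORN <- c("no", "yes")

#' Generative calibration of the device study
#'
#' Builds the effect model that drives every synthetic stage: amplitude cell
#' means by device and emotion, f0 cell means by device, emotion and sex,
#' amplitude sex offsets for the high-proximity devices, and within/
#' between-participant dispersions.
#'
#' The default amplitude cell means are the study's device-by-emotion means
#' (e.g. lavalier-happy 64.54 dB, laptop-sad 45.05 dB). Female f0 cell means
#' are not all reported directly, so they are derived from the 50/50 sex
#' balance as `2 * pooled_device_mean - male_device_mean` and spread across
#' emotions proportionally to the pooled device-by-emotion means. Amplitude
#' sex offsets are set from the reported lavalier/headset sex means and zero
#' elsewhere. Within-recording amplitude dispersion is per-device, elevated
#' for the lavalier (high-proximity amplitude is both inflated and more
#' dispersed); within-recording f0 dispersion is elevated for the smartphone
#' (its f0 capture is distorted by onboard filtering).
#'
#' @param sigma_amp_within Within-recording amplitude SD in dB: scalar or
#'   named per-device vector. Default 4.5 dB, lavalier 6.5 dB.
#' @param sigma_f0_within Within-recording f0 SD in Hz: scalar or named
#'   per-device vector. Default 12 Hz, smartphone 18 Hz.
#' @param sigma_amp_participant,sigma_f0_participant Between-participant
#'   random-intercept SDs (2.5 dB, 10 Hz).
#' @param amp_mean Optional device x emotion matrix of amplitude means (dB)
#'   overriding the default calibration.
#' @param f0_mean Optional device x emotion x sex array of f0 means (Hz).
#' @param amp_sex_offset Optional device x sex matrix of amplitude offsets (dB).
#' @return An object of class `effect_model`.
#' @export
default_effect_model <- function(sigma_amp_within = NULL,
                                 sigma_f0_within = NULL,
                                 sigma_amp_participant = 2.5,
                                 sigma_f0_participant = 10,
                                 amp_mean = NULL, f0_mean = NULL,
                                 amp_sex_offset = NULL) {
  if (is.null(amp_mean)) {
    amp_mean <- rbind(
      baseline   = c(57.47, 59.70, 55.86),
      lavalier   = c(63.72, 64.54, 62.73),
      headset    = c(59.41, 61.62, 58.16),
      smartphone = c(52.75, 55.12, 50.82),
      laptop     = c(46.79, 48.88, 45.05))
    colnames(amp_mean) <- EMOTIONS
  }
  if (is.null(f0_mean)) {
    pooled <- rbind(
      baseline   = c(163.74, 188.38, 155.82),
      lavalier   = c(165.93, 190.96, 155.69),
      headset    = c(165.35, 190.56, 156.73),
      smartphone = c(175.50, 203.35, 163.26),
      laptop     = c(162.99, 186.72, 155.55))
    colnames(pooled) <- EMOTIONS
    male_dev <- c(baseline = 120.64, lavalier = 124.60, headset = 123.96,
                  smartphone = 141.06, laptop = 119.42)
    pooled_dev <- rowMeans(pooled)
    female_dev <- 2 * pooled_dev - male_dev
    f0_mean <- array(NA_real_, dim = c(nrow(pooled), ncol(pooled), 2L),
                     dimnames = list(rownames(pooled), EMOTIONS, SEXES))
    for (d in rownames(pooled)) {
      shape <- pooled[d, ] / pooled_dev[[d]]
      f0_mean[d, , "female"] <- female_dev[[d]] * shape
      f0_mean[d, , "male"] <- male_dev[[d]] * shape
    }
  }
  if (is.null(amp_sex_offset)) {
    amp_sex_offset <- matrix(0, nrow = nrow(amp_mean), ncol = 2L,
                             dimnames = list(rownames(amp_mean), SEXES))
    amp_sex_offset["lavalier", ] <- c(female = 65.62 - 63.68,
                                      male = 61.71 - 63.68)
    amp_sex_offset["headset", ] <- c(female = 59.91 - 59.73,
                                     male = 59.55 - 59.73)
  }
  devices <- rownames(amp_mean)
  expand_sigma <- function(x, default, special = NULL) {
    out <- stats::setNames(rep(default, length(devices)), devices)
    if (!is.null(special)) out[names(special)] <- special
    if (!is.null(x)) {
      if (is.null(names(x))) out[] <- x else out[names(x)] <- x
    }
    if (any(out < 0)) stop("dispersions must be nonnegative")
    out
  }
  model <- structure(list(
    devices = devices, emotions = colnames(amp_mean), sexes = SEXES,
    amp_mean = amp_mean, f0_mean = f0_mean, amp_sex_offset = amp_sex_offset,
    sigma_amp_within = expand_sigma(sigma_amp_within, 4.5, c(lavalier = 6.5)),
    sigma_f0_within = expand_sigma(sigma_f0_within, 12, c(smartphone = 18)),
    sigma_amp_participant = sigma_amp_participant,
    sigma_f0_participant = sigma_f0_participant,
    perturb = list(sd_f0 = c(log(20), 0.25), sd_amp = c(log(4), 0.25),
                   jitter = c(log(0.012), 0.3), shimmer = c(log(0.06), 0.3))),
    class = "effect_model")
  if (sigma_amp_participant < 0 || sigma_f0_participant < 0)
    stop("dispersions must be nonnegative")
  model
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n  amplitude cell means (dB):\n")
  print(round(x$amp_mean, 2))
  cat(sprintf("  sigma_amp_within: %s dB; sigma_f0_within: %s Hz\n",
              paste(x$sigma_amp_within, collapse = "/"),
              paste(x$sigma_f0_within, collapse = "/")))
  cat(sprintf("  participant SDs: %.1f dB, %.1f Hz\n",
              x$sigma_amp_participant, x$sigma_f0_participant))
  invisible(x)
}

#' Generate the nested within-subjects study design
#'
#' Full factorial within participant: 5 devices x 3 emotions x 2 phrases x
#' 2 headset conditions = 60 recordings per participant, sexes balanced
#' across participants. The emotion task order is recorded per participant:
#' neutral always first, then happy/sad in randomized order.
#'
#' @param n_participants Even participant count (default 30, the study size,
#'   giving 1,800 rows).
#' @param seed Integer seed for the emotion-order randomization.
#' @return A data.frame with one row per recording: `participant_id`, `sex`,
#'   `device`, `emotion`, `phrase`, `headset_worn`, `emotion_rank`.
#' @export
generate_design <- function(n_participants = 30L, seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 2L || n_participants %% 2L != 0L)
    stop("n_participants must be even (sex-balanced) and at least 2")
  ids <- sprintf("P%03d", seq_len(n_participants))
  sexes <- rep(SEXES, length.out = n_participants)
  per <- expand.grid(device = DEVICES, emotion = EMOTIONS, phrase = PHRASES,
                     headset_worn = HEADSET_WORN,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  orders <- with_seed(seed, lapply(seq_len(n_participants), function(i) {
    c(neutral = 1L, sample(stats::setNames(2:3, c("happy", "sad"))))
  }))
  design <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    d <- per
    d$participant_id <- ids[i]
    d$sex <- sexes[i]
    d$emotion_rank <- orders[[i]][d$emotion]
    d
  }))
  rownames(design) <- NULL
  design[, c("participant_id", "sex", "device", "emotion", "phrase",
             "headset_worn", "emotion_rank")]
}

#' Sample a feature table from the generative model
#'
#' Draws per-recording features conditioned on device, emotion and sex:
#' `mean_amp_db = amp_mean[d,e] + amp_sex_offset[d,s] + b_amp(p) + eps` and
#' `mean_f0_hz = f0_mean[d,e,s] + b_f0(p) + eps`, with participant random
#' intercepts `b ~ N(0, sigma_participant)` drawn once per participant and
#' within-recording noise `eps ~ N(0, sigma_within[device])`. Perturbation
#' covariates (`sd_f0_hz`, `sd_amp_db`, `jitter_local`, `shimmer_local`) are
#' drawn from configured lognormal distributions.
#'
#' @param design A design from [generate_design()].
#' @param model An [default_effect_model()] calibration.
#' @param seed Integer seed.
#' @return The design with feature columns appended (a feature table), plus
#'   a `recording_id` key.
#' @export
sample_features <- function(design, model = default_effect_model(), seed = 1L) {
  stopifnot(inherits(model, "effect_model"))
  missing_dev <- setdiff(unique(design$device), model$devices)
  if (length(missing_dev))
    stop("effect model has no cell for device: ",
         paste(missing_dev, collapse = ", "))
  missing_emo <- setdiff(unique(design$emotion), model$emotions)
  if (length(missing_emo))
    stop("effect model has no cell for emotion: ",
         paste(missing_emo, collapse = ", "))

  n <- nrow(design)
  ids <- unique(design$participant_id)
  with_seed(seed, {
    b_amp <- stats::setNames(
      stats::rnorm(length(ids), 0, model$sigma_amp_participant), ids)
    b_f0 <- stats::setNames(
      stats::rnorm(length(ids), 0, model$sigma_f0_participant), ids)
    dev <- design$device
    amp_mu <- model$amp_mean[cbind(dev, design$emotion)] +
      model$amp_sex_offset[cbind(dev, design$sex)] +
      b_amp[design$participant_id]
    f0_mu <- model$f0_mean[cbind(dev, design$emotion, design$sex)] +
      b_f0[design$participant_id]
    out <- design
    out$mean_amp_db <- amp_mu + stats::rnorm(n, 0, model$sigma_amp_within[dev])
    out$mean_f0_hz <- f0_mu + stats::rnorm(n, 0, model$sigma_f0_within[dev])
    pp <- model$perturb
    out$sd_f0_hz <- stats::rlnorm(n, pp$sd_f0[1], pp$sd_f0[2])
    out$sd_amp_db <- stats::rlnorm(n, pp$sd_amp[1], pp$sd_amp[2])
    out$jitter_local <- stats::rlnorm(n, pp$jitter[1], pp$jitter[2])
    out$shimmer_local <- stats::rlnorm(n, pp$shimmer[1], pp$shimmer[2])
    out$n_voiced_frames <- stats::rpois(n, 60)
    out$recording_id <- with(out, paste(participant_id, device, emotion,
                                        phrase, headset_worn, sep = "_"))
    out
  })
}

#' Synthesize a harmonic vowel fixture
#'
#' Sum of `n_harmonics` harmonics with amplitudes proportional to `1/h`,
#' generated cycle by cycle so that each pitch period can be perturbed
#' multiplicatively by `Normal(1, jitter)`, then rescaled to the target RMS.
#' Intended as a ground-truth fixture for the feature extractor.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param rms Target root-mean-square amplitude, in `(0, 1/sqrt(2))`.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param n_harmonics Number of harmonics (aliasing guard:
#'   `f0 * n_harmonics < rate / 2`).
#' @param jitter Multiplicative SD of the period perturbation.
#' @param seed Integer seed for the period perturbations.
#' @return An [audio_clip()].
#' @export
synth_vowel <- function(f0, rms, duration = 1, rate = 44100, n_harmonics = 5L,
                        jitter = 0, seed = 1L) {
  if (f0 * n_harmonics >= rate / 2)
    stop("aliasing: f0 * n_harmonics must be below the Nyquist frequency")
  if (rms <= 0 || rms >= 1 / sqrt(2))
    stop("rms must lie in (0, 1/sqrt(2))")
  n_total <- round(duration * rate)
  x <- numeric(n_total)
  with_seed(seed, {
    t_start <- 0
    while (t_start < duration) {
      t_per <- (1 / f0) * max(0.2, stats::rnorm(1L, 1, jitter))
      i0 <- floor(t_start * rate) + 1L
      i1 <- min(n_total, ceiling((t_start + t_per) * rate))
      if (i0 > n_total) break
      tt <- ((i0:i1) - 1) / rate - t_start
      tt <- tt[tt < t_per]
      if (length(tt)) {
        idx <- i0 + seq_along(tt) - 1L
        cyc <- numeric(length(tt))
        for (h in seq_len(n_harmonics))
          cyc <- cyc + sin(2 * pi * h * tt / t_per) / h
        x[idx] <- cyc
      }
      t_start <- t_start + t_per
    }
  })
  x <- x * rms / sqrt(mean(x^2))
  audio_clip(x, rate)
}
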