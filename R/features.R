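#' @section Feature extraction:
#' The extractor works framewise: overlapping Hann-windowed frames, a
#' normalized autocorrelation pitch candidate per frame (parabolic peak
#' interpolation for sub-sample lag resolution), and an energy-based
#' intensity per frame on the dB scale re 2e-5 pressure units.
#' @name voicebias-features
NULL

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L))

frame_starts <- function(n, frame_n, hop_n) {
  if (n < frame_n) stop("insufficient signal: clip shorter than one analysis frame")
  seq.int(1L, n - frame_n + 1L, by = hop_n)
}

# Hann-weighted mean-square power of each frame (columns of `mat`).
frame_powers <- function(mat, w) {
  as.numeric(crossprod(mat^2, w)) / sum(w)
}

frames_matrix <- function(x, starts, frame_n) {
  idx <- outer(seq.int(0L, frame_n - 1L), starts, `+`)
  matrix(x[idx], nrow = frame_n)
}

#' Fundamental-frequency contour
#'
#' Estimates a per-frame f0 by maximizing the normalized autocorrelation of
#' the Hann-windowed, mean-removed frame over candidate lags
#' `[rate/f_max, rate/f_min]`, refined by parabolic interpolation. A frame
#' is marked unvoiced when the normalized peak falls below
#' `voicing_threshold`, when its power lies more than 30 dB below the
#' loudest frame (silence floor), or when the refined f0 leaves the search
#' band. Ties between equal peaks resolve to the lowest lag (highest f0).
#'
#' @param clip An [audio_clip()].
#' @param f_min,f_max Pitch search band in Hz; defaults 75 and 500 Hz cover
#'   adult speaking ranges (male roughly 85-155 Hz, female 165-255 Hz).
#' @param frame_len Frame length in seconds (default 0.04; must be at least
#'   `2 / f_min`).
#' @param hop Hop between frame starts in seconds (default 0.01).
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.45).
#' @return A data.frame of class `f0_contour` with columns `time` (frame
#'   center, s), `f0` (Hz, `NA` when unvoiced) and `voiced`.
#' @export
f0_contour <- function(clip, f_min = 75, f_max = 500, frame_len = 0.04,
                       hop = 0.01, voicing_threshold = 0.45) {
  stopifnot(inherits(clip, "audio_clip"))
  rate <- clip$rate
  if (!(f_min > 0 && f_min < f_max && f_max < rate / 2))
    stop("need 0 < f_min < f_max < rate/2")
  if (frame_len < 2 / f_min)
    stop("frame_len must be at least 2/f_min to hold two pitch periods")
  x <- clip$samples
  frame_n <- round(frame_len * rate)
  hop_n <- max(1L, round(hop * rate))
  starts <- frame_starts(length(x), frame_n, hop_n)
  w <- hann(frame_n)
  fr <- frames_matrix(x, starts, frame_n)
  powers <- frame_powers(fr, w)
  floor_power <- max(powers) * 10^(-30 / 10)

  lag_min <- max(2L, floor(rate / f_max))
  lag_max <- min(frame_n - 1L, ceiling(rate / f_min))
  m <- stats::nextn(2L * frame_n, 2)

  f0 <- rep(NA_real_, length(starts))
  for (j in seq_along(starts)) {
    if (powers[j] <= floor_power || powers[j] == 0) next
    s <- fr[, j]
    s <- (s - mean(s)) * w
    ft <- stats::fft(c(s, numeric(m - frame_n)))
    rxx <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / m
    cs <- cumsum(s^2)
    tot <- cs[frame_n]
    lags <- lag_min:lag_max
    e1 <- cs[frame_n - lags]
    e2 <- tot - cs[lags]
    denom <- sqrt(e1 * e2)
    r <- ifelse(denom > 0, rxx[lags + 1L] / denom, 0)
    k <- which.max(r)
    peak <- r[k]
    lag <- lags[k]
    if (k > 1L && k < length(r)) {
      rm1 <- r[k - 1L]; rp1 <- r[k + 1L]
      den <- rm1 - 2 * peak + rp1
      if (den < 0) {
        delta <- 0.5 * (rm1 - rp1) / den
        peak <- peak - 0.25 * (rm1 - rp1) * delta
        lag <- lag + delta
      }
    }
    cand <- rate / lag
    if (peak >= voicing_threshold && cand >= f_min && cand <= f_max)
      f0[j] <- cand
  }
  out <- data.frame(time = (starts - 1 + (frame_n - 1) / 2) / rate,
                    f0 = f0, voiced = !is.na(f0))
  class(out) <- c("f0_contour", "data.frame")
  out
}

#' Intensity contour
#'
#' Per-frame intensity in dB re 2e-5 pressure units:
#' `10 * log10(mean_w(x^2) / (2e-5)^2)` with Hann-weighted mean square.
#' All-zero frames are flagged `silent` (intensity `-Inf`), not an error.
#'
#' @inheritParams f0_contour
#' @return A data.frame of class `intensity_contour` with columns `time`,
#'   `intensity_db` and `silent`.
#' @export
intensity_contour <- function(clip, frame_len = 0.04, hop = 0.01) {
  stopifnot(inherits(clip, "audio_clip"))
  rate <- clip$rate
  frame_n <- round(frame_len * rate)
  hop_n <- max(1L, round(hop * rate))
  starts <- frame_starts(length(clip$samples), frame_n, hop_n)
  w <- hann(frame_n)
  powers <- frame_powers(frames_matrix(clip$samples, starts, frame_n), w)
  silent <- powers == 0
  db <- ifelse(silent, -Inf, db_from_power(powers))
  out <- data.frame(time = (starts - 1 + (frame_n - 1) / 2) / rate,
                    intensity_db = db, silent = silent)
  class(out) <- c("intensity_contour", "data.frame")
  out
}

# Mark successive waveform peaks (one per pitch period) with parabolic
# sub-sample refinement, guided by a nominal period of `t0` samples.
mark_periods <- function(x, t0, from = 1L, to = length(x)) {
  pos <- numeric(0)
  height <- numeric(0)
  win_end <- min(to, from + ceiling(1.5 * t0))
  seg <- x[from:win_end]
  i <- from - 1L + which.max(seg)
  repeat {
    p <- as.numeric(i); h <- x[i]
    if (i > 1L && i < length(x)) {
      ym <- x[i - 1L]; y0 <- x[i]; yp <- x[i + 1L]
      den <- ym - 2 * y0 + yp
      if (den < 0) {
        delta <- 0.5 * (ym - yp) / den
        p <- i + delta
        h <- y0 - 0.25 * (ym - yp) * delta
      }
    }
    pos <- c(pos, p); height <- c(height, h)
    lo <- i + max(2L, round(0.7 * t0))
    hi <- i + round(1.3 * t0)
    if (hi > to) break
    i <- lo - 1L + which.max(x[lo:hi])
  }
  list(pos = pos, height = height)
}

#' Per-recording voice features
#'
#' Summarizes an f0 contour, an intensity contour and the underlying clip
#' into the per-recording features used by all downstream statistics:
#' mean/SD f0 over voiced frames, energy-averaged mean intensity and dB-scale
#' intensity SD over non-silent frames above the silence floor (30 dB below
#' the loudest frame), and local jitter/shimmer measured on consecutive
#' pitch-period peaks of the waveform.
#'
#' `jitter_local` is the mean absolute difference of consecutive pitch
#' periods divided by the mean period; `shimmer_local` the analogous ratio
#' on consecutive period peak amplitudes.
#'
#' @param f0c An [f0_contour()].
#' @param ic An [intensity_contour()] from the same clip.
#' @param clip The [audio_clip()] both contours were computed from.
#' @return A one-row data.frame of class `voice_features` with columns
#'   `mean_f0_hz`, `sd_f0_hz`, `mean_amp_db`, `sd_amp_db`, `jitter_local`,
#'   `shimmer_local`, `n_voiced_frames`.
#' @export
summarize_features <- function(f0c, ic, clip) {
  stopifnot(inherits(f0c, "f0_contour"), inherits(ic, "intensity_contour"),
            inherits(clip, "audio_clip"))
  keep <- !ic$silent & ic$intensity_db >= max(ic$intensity_db) - 30
  mean_amp <- 10 * log10(mean(10^(ic$intensity_db[keep] / 10)))
  sd_amp <- stats::sd(ic$intensity_db[keep])

  voiced <- f0c$voiced
  n_voiced <- sum(voiced)
  if (n_voiced == 0L) {
    warning("no voiced frames; f0, jitter and shimmer are undefined")
    mean_f0 <- sd_f0 <- jitter <- shimmer <- NA_real_
  } else {
    vf <- f0c$f0[voiced]
    mean_f0 <- mean(vf)
    sd_f0 <- if (n_voiced > 1L) stats::sd(vf) else 0
    t0 <- clip$rate / stats::median(vf)
    from <- max(1L, floor(min(f0c$time[voiced]) * clip$rate))
    to <- min(length(clip$samples),
              ceiling(max(f0c$time[voiced]) * clip$rate))
    mk <- mark_periods(clip$samples, t0, from, to)
    if (length(mk$pos) >= 3L) {
      periods <- diff(mk$pos) / clip$rate
      jitter <- mean(abs(diff(periods))) / mean(periods)
      heights <- mk$height[-1L] # first peak can sit on a window edge
      shimmer <- if (length(heights) >= 3L)
        mean(abs(diff(heights))) / mean(heights) else NA_real_
    } else {
      jitter <- shimmer <- NA_real_
    }
  }
  out <- data.frame(mean_f0_hz = mean_f0, sd_f0_hz = sd_f0,
                    mean_amp_db = mean_amp, sd_amp_db = sd_amp,
                    jitter_local = jitter, shimmer_local = shimmer,
                    n_voiced_frames = n_voiced)
  class(out) <- c("voice_features", "data.frame")
  out
}

#' One-call feature extraction from a clip
#'
#' Convenience wrapper: [f0_contour()] + [intensity_contour()] +
#' [summarize_features()].
#'
#' @inheritParams f0_contour
#' @return A `voice_features` row; see [summarize_features()].
#' @export
extract_features <- function(clip, f_min = 75, f_max = 500, frame_len = 0.04,
                             hop = 0.01, voicing_threshold = 0.45) {
  f0c <- f0_contour(clip, f_min, f_max, frame_len, hop, voicing_threshold)
  ic <- intensity_contour(clip, frame_len, hop)
  summarize_features(f0c, ic, clip)
}
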