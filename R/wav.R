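#' Audio clip container
#'
#' A minimal container for a mono waveform: a numeric vector of samples on
#' the dimensionless pressure scale (full scale = 1) plus a sampling rate.
#'
#' @param samples Numeric vector of finite samples in `[-1, 1]`.
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `audio_clip` with elements `samples` and `rate`.
#' @export
audio_clip <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio clip must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio clip samples must all be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sampling rate must be a single positive number")
  structure(list(samples = samples, rate = rate), class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Read a RIFF/WAV file
#'
#' Reads PCM integer (16-bit) and IEEE float (32-bit) little-endian WAV
#' files. Integer samples are normalized to `[-1, 1]`; stereo is downmixed
#' to mono by averaging the channels.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAV file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, size = 2L,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, size = 2L,
                               signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1L, size = 4L,
                               endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, size = 2L,
                               signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV file (missing fmt or data chunk): ", path)
  if (length(data_raw) == 0L) stop("WAV file contains no samples: ", path)

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                 endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d-bit); only PCM 16-bit and IEEE float 32-bit are handled",
                 fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_clip(x, fmt$sample_rate)
}

#' Write a RIFF/WAV file
#'
#' Writes a mono or multi-channel waveform as PCM 16-bit or IEEE float
#' 32-bit little-endian WAV.
#'
#' @param samples Numeric vector (mono) or matrix with one channel per row.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM integer) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = c(32L, 16L)) {
  bits <- as.integer(bits[1L])
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  if (is.matrix(samples)) {
    n_chan <- nrow(samples)
    x <- as.numeric(samples) # column-major = interleaved frames
  } else {
    n_chan <- 1L
    x <- as.numeric(samples)
  }
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2L, endian = "little")
  writeBin(n_chan, con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate) * n_chan * bytes_per, con, size = 4L,
           endian = "little")
  writeBin(n_chan * bytes_per, con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}
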