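#' Calibrated audio waveform
#'
#' A `waveform` is a numeric vector of sample amplitudes together with a
#' sampling rate and a sound-level calibration: a waveform with unit RMS
#' corresponds to `spl_ref_db` dB SPL (94 dB SPL by default). All stimulus
#' generators and the hearing-aid simulator operate on this type.
#'
#' @param samples numeric vector of amplitudes (finite).
#' @param rate_hz sampling rate in Hz (default 24414.0625).
#' @param spl_ref_db level in dB SPL corresponding to RMS 1 (default 94).
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, rate_hz = 24414.0625, spl_ref_db = 94) {
  stopifnot(is.numeric(samples), rate_hz > 0)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 spl_ref_db = spl_ref_db),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %.4f Hz (%.3f s), level %.1f dB SPL\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              tryCatch(measure_level(x), error = function(e) NA_real_)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

rms <- function(x) sqrt(mean(x^2))

#' Measure the calibrated level of a waveform
#'
#' @param w a [waveform].
#' @return level in dB SPL, using the RMS-1 = `spl_ref_db` convention.
#' @export
measure_level <- function(w) {
  stopifnot(inherits(w, "waveform"))
  r <- rms(w$samples)
  if (r == 0) stop("cannot measure the level of a silent waveform")
  w$spl_ref_db + 20 * log10(r)
}

#' Scale a waveform to a target sound level
#'
#' Rescales the samples so that the waveform's RMS corresponds to `level_db`
#' dB SPL under its calibration (RMS 1 = 94 dB SPL by default). Re-scaling is
#' idempotent in level: `set_level(set_level(w, L), L)` equals `set_level(w, L)`.
#'
#' @param w a [waveform] with nonzero RMS.
#' @param level_db target level in dB SPL.
#' @return a [waveform] with RMS `10^((level_db - spl_ref_db)/20)`.
#' @export
set_level <- function(w, level_db) {
  stopifnot(inherits(w, "waveform"))
  r <- rms(w$samples)
  if (r == 0) stop("cannot set the level of a silent waveform")
  target_rms <- 10^((level_db - w$spl_ref_db) / 20)
  waveform(w$samples * (target_rms / r), w$rate_hz, w$spl_ref_db)
}

# 10 ms raised-cosine on/off ramps, in place; plateau amplitude untouched.
apply_ramps <- function(x, rate_hz, ramp_s = 0.010) {
  n <- length(x)
  nr <- min(round(ramp_s * rate_hz), floor(n / 2))
  if (nr > 0) {
    # ramp starts at exactly zero
    r <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1) / nr)
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[n - seq_len(nr) + 1] <- x[n - seq_len(nr) + 1] * r
  }
  x
}

# Bandpass Gaussian noise synthesized in the frequency domain: out-of-band
# bins zeroed, in-band bins given unit magnitude and uniform random phase.
band_noise <- function(n, rate_hz, f_lo, f_hi) {
  stopifnot(f_hi > f_lo, f_hi <= rate_hz / 2)
  np <- nextn(n, 2)                # fast (even) FFT length; truncate after
  freqs <- (0:(np - 1)) * rate_hz / np
  half <- freqs[seq_len(np / 2 + 1)]
  mag <- as.numeric(half >= f_lo & half <= f_hi)
  ph <- runif(length(half), 0, 2 * pi)
  spec_half <- mag * exp(1i * ph)
  spec_half[1] <- 0
  spec_half[length(spec_half)] <- Re(spec_half[length(spec_half)])
  spec <- c(spec_half, Conj(rev(spec_half[2:(np / 2)])))
  x <- Re(fft(spec, inverse = TRUE) / np)[seq_len(n)]
  x / max(rms(x), .Machine$double.eps)
}

# Analytic-signal magnitude (Hilbert envelope) via the frequency domain.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Write a waveform to a 32-bit float WAV file
#'
#' Minimal single-channel IEEE-float WAV writer (no compression, no metadata).
#'
#' @param w a [waveform].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(w$rate_hz))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(w$samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @param rate_hz exact sampling rate to attach (WAV headers store integer
#'   rates; defaults to the header value).
#' @param spl_ref_db calibration reference (default 94).
#' @return a [waveform].
#' @export
read_wav <- function(path, rate_hz = NULL, spl_ref_db = 94) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  stopifnot(riff == "RIFF")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  stopifnot(readChar(con, 4) == "WAVE")
  rate <- NA_real_; fmt <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      if (fmt != 3) stop("only IEEE-float WAV is supported")
      samples <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      break
    } else invisible(readBin(con, "raw", sz))
  }
  if (is.null(samples)) stop("no data chunk found")
  waveform(samples, if (is.null(rate_hz)) rate else rate_hz, spl_ref_db)
}
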