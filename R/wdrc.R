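#' Wide-dynamic-range-compression (WDRC) hearing-aid configuration
#'
#' Ten-channel compressor. Below a channel's compression threshold (knee),
#' gain is the channel's linear gain; above it, output level rises 1 dB per
#' `ratio` dB of input level. Level estimation uses a one-pole power follower
#' with 5 ms attack / 40 ms release time constants.
#'
#' @param gains_db per-channel linear gains in dB (length 10).
#' @param ratios per-channel compression ratios, all >= 1 (length 10).
#' @param crossovers_hz 9 ascending crossover frequencies between channels.
#' @param thresholds_db_spl per-channel compression knees in dB SPL.
#' @param attack_ms,release_ms level-estimator time constants (5 / 40 ms).
#' @return an object of class `wdrc_config`.
#' @export
wdrc_config <- function(gains_db = c(10, 10, 12, 15, 18, 21, 24, 27, 30, 30),
                        ratios = c(1, 1, 1.2, 1.5, 1.8, 2, 2.2, 2.5, 2.5, 2.5),
                        crossovers_hz = c(200, 500, 1000, 1750, 2750, 4000,
                                          5500, 7000, 8500),
                        thresholds_db_spl = c(45, 43, 40, 38, 35, 33, 28, 30,
                                              36, 44),
                        attack_ms = 5, release_ms = 40) {
  stopifnot(length(crossovers_hz) == 9, !is.unsorted(crossovers_hz),
            length(gains_db) == 10, length(ratios) == 10,
            length(thresholds_db_spl) == 10)
  if (any(ratios < 1)) stop("compression ratios must be >= 1")
  if (!(attack_ms < release_ms)) stop("attack must be faster than release")
  structure(list(gains_db = gains_db, ratios = ratios,
                 crossovers_hz = crossovers_hz,
                 thresholds_db_spl = thresholds_db_spl,
                 attack_ms = attack_ms, release_ms = release_ms),
            class = "wdrc_config")
}

# Channel band edges: 0 | crossovers | Nyquist.
wdrc_band_edges <- function(cfg, rate_hz) {
  c(0, cfg$crossovers_hz, rate_hz / 2)
}

# Nominal channel center frequencies (geometric mean of band edges; the
# lowest edge is floored at 50 Hz so the first center is finite).
wdrc_band_centers <- function(cfg, rate_hz) {
  e <- wdrc_band_edges(cfg, rate_hz)
  sqrt(pmax(e[-length(e)], 50) * e[-1])
}

# Zero-phase complementary band split in the frequency domain: each FFT bin
# is assigned to exactly one channel, so the bands sum to the input exactly.
wdrc_band_split <- function(x, cfg, rate_hz) {
  n <- length(x)
  np <- nextn(n, c(2, 3, 5))       # pad for a fast mixed-radix FFT
  X <- fft(c(x, numeric(np - n)))
  freqs <- (0:(np - 1)) * rate_hz / np
  freqs <- pmin(freqs, rate_hz - freqs)     # mirror to [0, Nyquist]
  edges <- wdrc_band_edges(cfg, rate_hz)
  bands <- matrix(0, n, 10)
  idx <- findInterval(freqs, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (b in 1:10) {
    mask <- as.numeric(idx == b)
    bands[, b] <- Re(fft(X * mask, inverse = TRUE) / np)[seq_len(n)]
  }
  bands
}

#' Apply WDRC hearing-aid processing to a calibrated waveform
#'
#' The input is split into 10 complementary zero-phase bands, each band's
#' level is tracked by a one-pole power follower with the configured
#' attack/release constants, a level-dependent gain is applied per band, and
#' the bands are summed. Length is preserved and processing is causal within
#' each band (the band split itself is zero-phase).
#'
#' @param w a calibrated [waveform].
#' @param cfg a [wdrc_config].
#' @return the processed [waveform].
#' @export
wdrc_process <- function(w, cfg = wdrc_config()) {
  if (!inherits(w, "waveform")) stop("input must be a calibrated waveform")
  stopifnot(inherits(cfg, "wdrc_config"))
  x <- w$samples
  if (all(x == 0)) return(w)
  bands <- wdrc_band_split(x, cfg, w$rate_hz)
  a_att <- exp(-1 / (cfg$attack_ms / 1000 * w$rate_hz))
  a_rel <- exp(-1 / (cfg$release_ms / 1000 * w$rate_hz))
  out <- numeric(length(x))
  for (b in 1:10) {
    xb <- bands[, b]
    env <- cpp_env_follow(xb^2, a_att, a_rel)
    lev <- w$spl_ref_db + 10 * log10(pmax(env, 1e-20))
    knee <- cfg$thresholds_db_spl[b]
    gain <- cfg$gains_db[b] +
      pmax(lev - knee, 0) * (1 / cfg$ratios[b] - 1)
    out <- out + xb * 10^(gain / 20)
  }
  waveform(out, w$rate_hz, w$spl_ref_db)
}

#' Measure a channel's steady-state input-output curve
#'
#' Presents a long steady tone at the channel's band center at each input
#' level, lets the level estimator settle (probe duration covers more than
#' ten release time constants), and measures the settled output level. The
#' slope of the curve is 1 below the knee and 1/ratio above it.
#'
#' @param cfg a [wdrc_config].
#' @param channel channel index, 1-10.
#' @param input_levels probe levels in dB SPL.
#' @param rate_hz sampling rate.
#' @param probe_hz optional probe frequency; defaults to the band center.
#'   Must lie inside the channel's band.
#' @return data frame with `input_db`, `output_db`.
#' @export
static_io_curve <- function(cfg, channel, input_levels,
                            rate_hz = 24414.0625, probe_hz = NULL) {
  stopifnot(inherits(cfg, "wdrc_config"), channel %in% 1:10)
  edges <- wdrc_band_edges(cfg, rate_hz)
  if (is.null(probe_hz)) probe_hz <- wdrc_band_centers(cfg, rate_hz)[channel]
  if (probe_hz < edges[channel] || probe_hz > edges[channel + 1])
    stop("probe frequency outside the channel's band")
  dur <- max(1.0, 12 * cfg$release_ms / 1000)
  n <- round(dur * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  settle <- seq(round(0.7 * n), n)
  out <- vapply(input_levels, function(L) {
    probe <- waveform(sqrt(2) * sin(2 * pi * probe_hz * t) * 10^((L - 94) / 20),
                      rate_hz)
    y <- wdrc_process(probe, cfg)
    94 + 20 * log10(rms(y$samples[settle]))
  }, numeric(1))
  data.frame(input_db = input_levels, output_db = out)
}

#' Derive a WDRC fit from an audiogram
#'
#' Maps threshold elevations to per-channel gains with the half-gain rule
#' (gain = shift/2, capped at 30 dB) and to compression ratios increasing
#' with shift (ratio = 1 + shift/40, capped at 2.5). A sloping audiogram
#' therefore yields roughly 10 dB of gain at low frequencies rising to 30 dB
#' at high frequencies, with ratios between 1 and 2.5. Deterministic.
#'
#' @param profile a [hearing_profile].
#' @param rate_hz sampling rate used to place channel centers.
#' @return a [wdrc_config].
#' @export
fit_from_audiogram <- function(profile, rate_hz = 24414.0625) {
  stopifnot(inherits(profile, "hearing_profile"))
  shifts <- profile$shift_db
  if (any(shifts < 0)) {
    warning("negative threshold shifts clamped to 0")
    shifts <- pmax(shifts, 0)
  }
  cfg0 <- wdrc_config()
  centers <- wdrc_band_centers(cfg0, rate_hz)
  shift_c <- interp_shift(shifts, profile$freq_hz, centers)
  gains <- pmin(pmax(shift_c / 2, 0), 30)
  ratios <- pmin(pmax(1 + shift_c / 40, 1), 2.5)
  wdrc_config(gains_db = gains, ratios = ratios,
              crossovers_hz = cfg0$crossovers_hz,
              thresholds_db_spl = cfg0$thresholds_db_spl)
}

# Linear interpolation of threshold shift on a log-frequency axis, flat
# extrapolation beyond the audiogram's end frequencies.
interp_shift <- function(shifts, freqs, at_hz) {
  approx(log2(freqs), shifts, xout = log2(at_hz), rule = 2)$y
}
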