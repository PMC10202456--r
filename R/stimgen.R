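#' @section Stimulus streams:
#' All generators return a calibrated [waveform] plus a label table with one
#' row per segment (stimulus tokens and explicit silence pauses). Labels tile
#' the stream exactly: `onset_s` + `duration_s` of row *i* equals `onset_s`
#' of row *i + 1*.
#' @name stimgen
NULL

label_cols <- c("kind", "onset_s", "duration_s", "frequency_hz",
                "intensity_db_spl", "mod_freq_hz", "mod_depth",
                "consonant_id", "talker_id")

empty_labels <- function() {
  df <- data.frame(kind = character(), onset_s = numeric(),
                   duration_s = numeric(), frequency_hz = numeric(),
                   intensity_db_spl = numeric(), mod_freq_hz = numeric(),
                   mod_depth = numeric(), consonant_id = integer(),
                   talker_id = integer(), stringsAsFactors = FALSE)
  df
}

label_row <- function(kind, onset_s, duration_s, frequency_hz = NA,
                      intensity_db_spl = NA, mod_freq_hz = NA, mod_depth = NA,
                      consonant_id = NA, talker_id = NA) {
  data.frame(kind = kind, onset_s = onset_s, duration_s = duration_s,
             frequency_hz = frequency_hz, intensity_db_spl = intensity_db_spl,
             mod_freq_hz = mod_freq_hz, mod_depth = mod_depth,
             consonant_id = as.integer(consonant_id),
             talker_id = as.integer(talker_id), stringsAsFactors = FALSE)
}

# Assemble alternating token/pause segments into one stream + tiled labels.
build_stream <- function(segments, seg_labels, pause_s, rate_hz,
                         spl_ref_db = 94) {
  n_pause <- round(pause_s * rate_hz)
  out <- vector("list", 2 * length(segments))
  labels <- vector("list", 2 * length(segments))
  t0 <- 0
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    dur <- length(seg) / rate_hz
    lab <- seg_labels[[i]]
    lab$onset_s <- t0
    lab$duration_s <- dur
    out[[2 * i - 1]] <- seg
    labels[[2 * i - 1]] <- lab
    t0 <- t0 + dur
    out[[2 * i]] <- numeric(n_pause)
    labels[[2 * i]] <- label_row("silence", t0, n_pause / rate_hz)
    t0 <- t0 + n_pause / rate_hz
  }
  list(wave = waveform(unlist(out), rate_hz, spl_ref_db),
       labels = do.call(rbind, labels))
}

#' Pure-tone frequency grid (500 Hz to 8 kHz in 0.2-octave steps)
#' @return numeric vector of 21 frequencies in Hz.
#' @export
tone_freq_grid <- function() 500 * 2^(seq(0, 4, by = 0.2))

#' Narrowband center-frequency grid (500 Hz to 8 kHz in 0.5-octave steps)
#' @return numeric vector of 9 center frequencies in Hz.
#' @export
narrowband_cf_grid <- function() 500 * 2^(seq(0, 4, by = 0.5))

#' Intensity grid (25 to 100 dB SPL in 5 dB steps)
#' @return numeric vector of 16 levels in dB SPL.
#' @export
level_grid <- function() seq(25, 100, by = 5)

scaled_tone <- function(freq, level_db, duration_s, rate_hz, spl_ref_db = 94) {
  t <- seq_len(round(duration_s * rate_hz)) / rate_hz
  x <- sqrt(2) * sin(2 * pi * freq * t)          # unit RMS
  x * 10^((level_db - spl_ref_db) / 20)
}

#' Synthesize a calibrated pure-tone stream
#'
#' 100 ms tones (10 ms raised-cosine on/off ramps) at every frequency x level
#' combination, separated by 100 ms silent pauses, in an order randomized by
#' `seed`.
#'
#' @param freqs tone frequencies in Hz (default [tone_freq_grid()]).
#' @param levels intensities in dB SPL (default [level_grid()]).
#' @param rate_hz sampling rate.
#' @param seed integer seed controlling presentation order.
#' @param duration_s,pause_s tone and pause durations in seconds.
#' @return list with `wave` ([waveform]) and `labels` (data frame).
#' @export
make_tone_stream <- function(freqs = tone_freq_grid(), levels = level_grid(),
                             rate_hz = 24414.0625, seed = 1,
                             duration_s = 0.1, pause_s = 0.1) {
  if (max(freqs) > rate_hz / 2) stop("tone frequency above Nyquist")
  grid <- expand.grid(freq = freqs, level = levels)
  ord <- with_seed(substream_seed(seed, "tone_order"),
                   sample.int(nrow(grid)))
  grid <- grid[ord, ]
  segs <- lapply(seq_len(nrow(grid)), function(i) {
    apply_ramps(scaled_tone(grid$freq[i], grid$level[i], duration_s, rate_hz),
                rate_hz)
  })
  labs <- lapply(seq_len(nrow(grid)), function(i)
    label_row("tone", 0, 0, frequency_hz = grid$freq[i],
              intensity_db_spl = grid$level[i]))
  build_stream(segs, labs, pause_s, rate_hz)
}

sam_burst <- function(f_lo, f_hi, mod_freq, depth, level_db, duration_s,
                      rate_hz, spl_ref_db = 94) {
  n <- round(duration_s * rate_hz)
  carrier <- band_noise(n, rate_hz, f_lo, f_hi)
  t <- (seq_len(n) - 1) / rate_hz
  env <- 1 + depth * sin(2 * pi * mod_freq * t - pi / 2)
  x <- carrier * env
  x <- x / rms(x) * 10^((level_db - spl_ref_db) / 20)
  apply_ramps(x, rate_hz)
}

#' Synthesize sinusoidally amplitude-modulated (SAM) noise streams
#'
#' 100 ms bursts of 500-8000 Hz bandpass noise with a sinusoidal envelope.
#' In `freq_sweep` mode the modulation frequency ranges 10-240 Hz in 10 Hz
#' steps at modulation depth 1; in `depth_sweep` mode the depth ranges 0.1-1
#' in 20 logarithmic steps at 30 Hz.
#'
#' @param mode `"freq_sweep"` or `"depth_sweep"`.
#' @param levels intensities in dB SPL.
#' @param rate_hz sampling rate.
#' @param seed integer seed (carrier noise and presentation order).
#' @param band carrier band edges in Hz.
#' @return list with `wave` and `labels`.
#' @export
make_sam_stream <- function(mode = c("freq_sweep", "depth_sweep"),
                            levels = level_grid(), rate_hz = 24414.0625,
                            seed = 1, band = c(500, 8000)) {
  mode <- match.arg(mode)
  if (mode == "freq_sweep") {
    grid <- expand.grid(mod_freq = seq(10, 240, by = 10), depth = 1,
                        level = levels)
  } else {
    depths <- 10^seq(log10(0.1), 0, length.out = 20)
    grid <- expand.grid(mod_freq = 30, depth = depths, level = levels)
  }
  if (any(grid$depth <= 0 | grid$depth > 1)) stop("depth outside (0, 1]")
  ord <- with_seed(substream_seed(seed, "sam_order"), sample.int(nrow(grid)))
  grid <- grid[ord, ]
  segs <- with_seed(substream_seed(seed, "sam_noise"), {
    lapply(seq_len(nrow(grid)), function(i)
      sam_burst(band[1], band[2], grid$mod_freq[i], grid$depth[i],
                grid$level[i], 0.1, rate_hz))
  })
  labs <- lapply(seq_len(nrow(grid)), function(i)
    label_row("sam", 0, 0, intensity_db_spl = grid$level[i],
              mod_freq_hz = grid$mod_freq[i], mod_depth = grid$depth[i]))
  build_stream(segs, labs, 0.1, rate_hz)
}

# 1/f-power ("pink") envelope between 1 and 100 Hz, shifted so its trough is
# exactly zero, giving a (peak - trough)/peak modulation depth of 1.
pink_envelope <- function(n, rate_hz) {
  freqs <- (0:(n - 1)) * rate_hz / n
  half <- freqs[seq_len(floor(n / 2) + 1)]
  mag <- ifelse(half >= 1 & half <= 100, 1 / sqrt(pmax(half, 1)), 0)
  ph <- runif(length(half), 0, 2 * pi)
  spec_half <- mag * exp(1i * ph)
  spec_half[1] <- 0
  spec <- c(spec_half, Conj(rev(spec_half[2:(ceiling(n / 2))])))
  e <- Re(fft(spec, inverse = TRUE)) / n
  e <- e - min(e)
  if (max(e) == 0) e <- rep(1, n) else e <- e / max(e)
  e
}

#' Synthesize a narrowband target / masker pair
#'
#' Target: 0.5-octave bandpass noise at `target_cf` with a 20 Hz sinusoidal
#' envelope of depth 1. Masker: 0.5-octave bandpass noise at `masker_cf` with
#' a pink-noise envelope of depth (peak - trough)/peak = 1, level-matched to
#' the target. Both 100 ms with 10 ms ramps.
#'
#' @param target_cf,masker_cf center frequencies in Hz (use
#'   [narrowband_cf_grid()]).
#' @param level level in dB SPL for both waveforms.
#' @param rate_hz sampling rate.
#' @param seed integer seed.
#' @param duration_s burst duration.
#' @return list with `target` and `masker` ([waveform]s).
#' @export
make_narrowband_pair <- function(target_cf, masker_cf, level = 70,
                                 rate_hz = 24414.0625, seed = 1,
                                 duration_s = 0.1) {
  n <- round(duration_s * rate_hz)
  tgt <- with_seed(substream_seed(seed, "nb_target"), {
    x <- band_noise(n, rate_hz, target_cf * 2^-0.25, target_cf * 2^0.25)
    t <- (seq_len(n) - 1) / rate_hz
    x * (1 + sin(2 * pi * 20 * t - pi / 2))
  })
  msk <- with_seed(substream_seed(seed, "nb_masker"), {
    x <- band_noise(n, rate_hz, masker_cf * 2^-0.25, masker_cf * 2^0.25)
    x * pink_envelope(n, rate_hz)
  })
  tgt <- apply_ramps(tgt, rate_hz)
  msk <- apply_ramps(msk, rate_hz)
  list(target = set_level(waveform(tgt, rate_hz), level),
       masker = set_level(waveform(msk, rate_hz), level))
}

# Spectral class of each consonant id (fixed): sonorant/vowel-like,
# plosive, fricative -- mirroring the three broad classes of English
# consonant spectra.
consonant_class_map <- function(n_consonants = 22) {
  classes <- c(rep("vowel_like", 8), rep("plosive", 6), rep("fricative", 8))
  rep_len(classes, n_consonants)
}

synth_consonant_token <- function(class, consonant_id, talker_jit, duration_s,
                                  rate_hz) {
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  x <- switch(class,
    vowel_like = {
      f0 <- 110 * talker_jit$f0 * 2^((consonant_id %% 4) * 0.1)
      h <- 1:12
      amps <- 1 / h^1.5
      env <- exp(-t / (0.5 * duration_s))
      colSums(amps * sin(outer(h, t) * 2 * pi * f0 +
                           runif(length(h), 0, 2 * pi))) * (0.3 + 0.7 * env)
    },
    plosive = {
      burst <- band_noise(n, rate_hz, 300 * talker_jit$tilt,
                          min(10000, rate_hz / 2 * 0.98))
      decay <- exp(-t / (0.015 + 0.005 * (consonant_id %% 3)))
      burst * decay
    },
    fricative = {
      f_lo <- 4200 * talker_jit$tilt * 2^((consonant_id %% 4) * 0.08)
      band_noise(n, rate_hz, min(f_lo, 8000),
                 min(11000, rate_hz / 2 * 0.98))
    })
  # zero the token tail with a 2 ms linear ramp
  nr <- round(0.002 * rate_hz)
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * seq(1, 0, length.out = nr)
  x / max(rms(x), .Machine$double.eps)
}

#' Synthesize an isolated-consonant token stream
#'
#' Parametric 200 ms stand-in tokens in three spectral classes (vowel-like
#' harmonic, plosive transient, fricative high-frequency noise) with
#' per-talker parameter jitter, presented in random order with 175 ms pauses.
#' Each intensity in `levels` is presented as a separate block.
#'
#' @param n_consonants number of distinct consonant ids (default 22).
#' @param n_talkers number of talkers, i.e. instances per consonant per level
#'   (default 10).
#' @param levels block intensities in dB SPL (default 70).
#' @param rate_hz sampling rate.
#' @param seed integer seed.
#' @return list with `wave` and `labels`.
#' @export
make_consonant_tokens <- function(n_consonants = 22, n_talkers = 10,
                                  levels = 70, rate_hz = 24414.0625,
                                  seed = 1) {
  classes <- consonant_class_map(n_consonants)
  if (n_consonants < 3) stop("need at least as many consonants as spectral-class prototypes")
  talkers <- with_seed(substream_seed(seed, "talkers"), {
    lapply(seq_len(n_talkers), function(i)
      list(f0 = 2^runif(1, -0.3, 0.3), tilt = 2^runif(1, -0.15, 0.15)))
  })
  segs <- list(); labs <- list()
  for (level in levels) {
    grid <- expand.grid(cid = seq_len(n_consonants), tid = seq_len(n_talkers))
    ord <- with_seed(substream_seed(seed, paste0("cons_order", level)),
                     sample.int(nrow(grid)))
    grid <- grid[ord, ]
    block <- with_seed(substream_seed(seed, paste0("cons_tokens", level)), {
      lapply(seq_len(nrow(grid)), function(i) {
        cid <- grid$cid[i]
        x <- synth_consonant_token(classes[cid], cid, talkers[[grid$tid[i]]],
                                   0.2, rate_hz)
        x * 10^((level - 94) / 20)
      })
    })
    segs <- c(segs, block)
    labs <- c(labs, lapply(seq_len(nrow(grid)), function(i)
      label_row("consonant", 0, 0, intensity_db_spl = level,
                consonant_id = grid$cid[i], talker_id = grid$tid[i])))
  }
  build_stream(segs, labs, 0.175, rate_hz)
}

# O(n) centered moving average via cumulative sums (edges renormalized).
moving_avg <- function(x, k) {
  n <- length(x)
  k <- max(1, min(round(k), n))
  cs <- c(0, cumsum(x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (k - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

voice_stream <- function(n, rate_hz) {
  f0_base <- runif(1, 90, 220)
  # slowly drifting fundamental (smoothed noise, < a few Hz)
  drift <- moving_avg(rnorm(n), 4096)
  f0 <- f0_base * 2^(0.15 * drift / max(abs(drift), 1e-12))
  phase <- 2 * pi * cumsum(f0) / rate_hz
  h <- 1:10
  x <- colSums((1 / h^1.3) * sin(outer(h, phase)))
  # syllabic-rate (~2-8 Hz) amplitude fluctuation
  syl <- moving_avg(abs(rnorm(n)), rate_hz / 5)^2
  x <- x * syl / max(syl)
  x / max(rms(x), .Machine$double.eps)
}

#' Synthesize multi-talker speech babble
#'
#' Sum of `n_talkers` independent synthetic voice-like streams (drifting
#' harmonic complexes with syllabic-rate amplitude fluctuations), dominated by
#' low-frequency energy.
#'
#' @param n_talkers number of summed streams (default 16).
#' @param duration_s babble duration in seconds.
#' @param rate_hz sampling rate.
#' @param seed integer seed.
#' @return a [waveform].
#' @export
make_babble <- function(n_talkers = 16, duration_s = 1, rate_hz = 24414.0625,
                        seed = 1) {
  n <- round(duration_s * rate_hz)
  x <- numeric(n)
  for (k in seq_len(n_talkers)) {
    x <- x + with_seed(substream_seed(seed, paste0("babble", k)),
                       voice_stream(n, rate_hz))
  }
  waveform(x, rate_hz)
}

#' Synthesize a spectrally well-separated multiband probe scene
#'
#' Sum of bandpass-noise streams at log-spaced center frequencies, each with
#' an independent slowly varying envelope spanning a wide level range
#' (+/- `swing_db`/2 around the mean). Designed to drive distinct frequency
#' channels independently, e.g. for latent-dimensionality recovery studies.
#'
#' @param n_bands number of bands (center frequencies log-spaced 500 Hz to
#'   8 kHz).
#' @param duration_s scene duration in seconds.
#' @param rate_hz sampling rate.
#' @param seed integer seed.
#' @param bw_oct band bandwidth in octaves (default: 0.8 x band spacing,
#'   capped at 0.5).
#' @param swing_db peak-to-peak level swing of each band's envelope.
#' @return a [waveform].
#' @export
make_multiband_scene <- function(n_bands, duration_s, rate_hz = 24414.0625,
                                 seed = 1, bw_oct = NULL, swing_db = 80) {
  cfs <- latent_channel_cfs(n_bands)
  spacing <- if (n_bands > 1) 4 / (n_bands - 1) else 1
  if (is.null(bw_oct)) bw_oct <- min(0.5, 0.8 * spacing)
  n <- round(duration_s * rate_hz)
  x <- numeric(n)
  for (j in seq_len(n_bands)) {
    x <- x + with_seed(substream_seed(seed, paste0("scene", j)), {
      carrier <- band_noise(n, rate_hz, cfs[j] * 2^(-bw_oct / 2),
                            cfs[j] * 2^(bw_oct / 2))
      db <- moving_avg(rnorm(n), rate_hz / 4)
      db <- (swing_db / 2) * db / max(abs(db))
      carrier * 10^(db / 20)
    })
  }
  waveform(x, rate_hz)
}

#' Mix speech and noise at a target speech-to-noise ratio
#'
#' The noise is rescaled so that the RMS of the speech over its active
#' (nonsilent) samples exceeds the noise RMS by `snr_db` dB, then added.
#'
#' @param speech,noise [waveform]s at the same rate; noise at least as long
#'   as speech.
#' @param snr_db target speech-to-noise ratio in dB (default 3).
#' @return a [waveform] of the same length as `speech`.
#' @export
mix_at_snr <- function(speech, noise, snr_db = 3) {
  stopifnot(inherits(speech, "waveform"), inherits(noise, "waveform"))
  if (speech$rate_hz != noise$rate_hz) stop("sampling rates differ")
  if (length(noise) < length(speech)) stop("noise shorter than speech")
  active <- abs(speech$samples) > 0
  if (!any(active)) stop("speech waveform is silent")
  s_rms <- rms(speech$samples[active])
  nseg <- noise$samples[seq_along(speech$samples)]
  n_rms <- rms(nseg)
  if (n_rms == 0) stop("noise waveform is silent")
  target_n_rms <- s_rms / 10^(snr_db / 20)
  waveform(speech$samples + nseg * (target_n_rms / n_rms), speech$rate_hz,
           speech$spl_ref_db)
}

#' Write a stimulus label table to CSV
#' @param labels label data frame from a stream generator.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, label_cols], path, row.names = FALSE)
  invisible(path)
}
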