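test_that("level calibration round-trips within 0.01 dB and errors on silence", {
  set.seed(1)
  w <- waveform(rnorm(5000))
  for (L in c(25, 40, 74, 94, 100)) {
    expect_equal(measure_level(set_level(w, L)), L, tolerance = 0.01)
  }
  expect_equal(sqrt(mean(set_level(w, 94)$samples^2)), 1, tolerance = 1e-10)
  expect_equal(sqrt(mean(set_level(w, 74)$samples^2)), 0.1, tolerance = 1e-10)
  # idempotent re-scaling from a different starting RMS
  half <- waveform(0.5 * sin(2 * pi * 1000 * (1:4883) / 24414.0625))
  expect_equal(sqrt(mean(set_level(half, 94)$samples^2)), 1, tolerance = 1e-10)
  expect_error(set_level(waveform(numeric(100)), 70), "silent")
  expect_error(measure_level(waveform(numeric(10))), "silent")
})

test_that("tone stream covers the full frequency x level grid with exact tiling", {
  ts <- fixture("tone_stream", make_tone_stream(seed = 1))
  tones <- ts$labels[ts$labels$kind == "tone", ]
  expect_equal(nrow(tones), 21 * 16)
  expect_equal(length(unique(tones$frequency_hz)), 21)
  expect_equal(length(unique(tones$intensity_db_spl)), 16)
  # labels tile the stream without overlap
  lab <- ts$labels
  expect_equal(lab$onset_s[-1], head(lab$onset_s + lab$duration_s, -1),
               tolerance = 1e-9)
  expect_equal(tail(lab$onset_s + lab$duration_s, 1),
               length(ts$wave) / ts$wave$rate_hz, tolerance = 1e-9)
  # ramp starts at zero amplitude
  first_tone <- lab[lab$kind == "tone", ][1, ]
  i0 <- round(first_tone$onset_s * ts$wave$rate_hz) + 1
  expect_equal(ts$wave$samples[i0], 0)
  # plateau RMS matches the requested level
  seg <- ts$wave$samples[i0:(i0 + round(0.1 * ts$wave$rate_hz) - 1)]
  plateau <- seg[round(length(seg) * 0.25):round(length(seg) * 0.75)]
  expect_equal(94 + 20 * log10(sqrt(mean(plateau^2))),
               first_tone$intensity_db_spl, tolerance = 0.1)
  expect_error(make_tone_stream(freqs = 20000), "Nyquist")
})

test_that("SAM streams have the stated modulation grids and envelope depths", {
  sf <- make_sam_stream("freq_sweep", levels = 70, seed = 2)
  segs <- sf$labels[sf$labels$kind == "sam", ]
  expect_equal(sort(unique(segs$mod_freq_hz)), seq(10, 240, 10))
  sd_ <- make_sam_stream("depth_sweep", levels = c(60, 70, 75, 80), seed = 2)
  depths <- sort(unique(sd_$labels$mod_depth[sd_$labels$kind == "sam"]))
  expect_equal(length(depths), 20)
  expect_equal(depths, 10^seq(log10(0.1), 0, length.out = 20),
               tolerance = 1e-9)
  # measured envelope depth (sinusoid fit to the analytic envelope) within 5%
  rate <- sd_$wave$rate_hz
  for (target in depths[c(12, 20)]) {
    take <- sd_$labels[sd_$labels$kind == "sam" &
      abs(sd_$labels$mod_depth - target) < 1e-9, ][1:4, ]
    ests <- vapply(seq_len(nrow(take)), function(i) {
      i0 <- round(take$onset_s[i] * rate) + 1
      n <- round(take$duration_s[i] * rate)
      seg <- sd_$wave$samples[i0:(i0 + n - 1)]
      core <- seg[round(n * 0.15):round(n * 0.85)]   # skip ramps
      env <- icdyn:::analytic_envelope(core)
      tt <- seq_along(env) / rate
      fit <- lm(env ~ sin(2 * pi * 30 * tt) + cos(2 * pi * 30 * tt))
      b <- coef(fit)
      sqrt(b[2]^2 + b[3]^2) / b[1]
    }, numeric(1))
    expect_equal(mean(ests), mean(take$mod_depth), tolerance = 0.05)
  }
  # full modulation: envelope minima near zero
  b <- icdyn:::sam_burst(500, 8000, 30, 1, 70, 0.1, 24414.0625)
  env <- icdyn:::analytic_envelope(b)
  n <- length(env)
  core <- env[round(n * 0.15):round(n * 0.85)]
  expect_lt(min(core) / max(core), 0.1)
  expect_true(identical(make_sam_stream("freq_sweep", levels = 70, seed = 5)$wave$samples,
                        make_sam_stream("freq_sweep", levels = 70, seed = 5)$wave$samples))
})

test_that("narrowband pair is level matched with the stated grids and envelopes", {
  expect_equal(length(narrowband_cf_grid()), 9)
  p <- make_narrowband_pair(2000, 707.1, level = 70, seed = 3)
  expect_equal(measure_level(p$target), 70, tolerance = 0.01)
  expect_equal(measure_level(p$masker) - measure_level(p$target), 0,
               tolerance = 0.01)
  expect_equal(length(p$target), length(p$masker))
  # 20 Hz target envelope: autocorrelation of the envelope peaks at 50 ms
  env <- icdyn:::analytic_envelope(p$target$samples)
  rate <- p$target$rate_hz
  ac <- acf(env, lag.max = round(0.06 * rate), plot = FALSE)$acf
  lag_peak <- which.max(ac[round(0.035 * rate):round(0.06 * rate)]) +
    round(0.035 * rate) - 1
  expect_lt(abs(lag_peak / rate - 0.050), 0.004)
  # bandpass stimuli: dominant power inside the stated band (slightly widened
  # to admit modulation sidebands)
  for (pair in list(list(p$target, 2000), list(p$masker, 707.1))) {
    spec <- Mod(fft(pair[[1]]$samples))^2
    cf <- pair[[2]]
    n <- length(spec)
    freqs <- (0:(n - 1)) * rate / n
    half <- freqs <= rate / 2
    inband <- half & freqs >= cf * 2^-0.3 & freqs <= cf * 2^0.3
    expect_gt(sum(spec[inband]) / sum(spec[half]), 0.90)
  }
  # unenveloped band noise: >= 95% of power strictly inside the stated band
  set.seed(11)
  for (band in list(c(1000, 2000), c(500, 8000))) {
    x <- icdyn:::band_noise(2441, rate, band[1], band[2])
    spec <- Mod(fft(x))^2
    freqs <- (0:2440) * rate / 2441
    half <- freqs <= rate / 2
    inband <- half & freqs >= band[1] & freqs <= band[2]
    expect_gt(sum(spec[inband]) / sum(spec[half]), 0.95)
  }
})

test_that("consonant tokens form labeled spectral classes with talker jitter", {
  ct <- fixture("cons_stream", make_consonant_tokens(seed = 4))
  segs <- ct$labels[ct$labels$kind == "consonant", ]
  expect_equal(length(unique(segs$consonant_id)), 22)
  expect_true(all(table(segs$consonant_id) >= 10))
  # fricative-class token: >= 70% of power above 4 kHz
  rate <- ct$wave$rate_hz
  fric_ids <- which(icdyn:::consonant_class_map(22) == "fricative")
  seg <- segs[segs$consonant_id == fric_ids[1], ][1, ]
  i0 <- round(seg$onset_s * rate) + 1
  x <- ct$wave$samples[i0:(i0 + round(seg$duration_s * rate) - 1)]
  p <- Mod(fft(x))^2
  freqs <- (0:(length(x) - 1)) * rate / length(x)
  half <- freqs <= rate / 2
  expect_gt(sum(p[half & freqs > 4000]) / sum(p[half]), 0.70)
  # determinism
  ct2 <- make_consonant_tokens(seed = 4)
  expect_identical(ct$wave$samples, ct2$wave$samples)
  expect_identical(ct$labels, ct2$labels)
  expect_error(make_consonant_tokens(n_consonants = 2), "prototypes")
})

test_that("babble is low-frequency dominated and sums incoherently", {
  b16 <- make_babble(n_talkers = 16, duration_s = 2, seed = 6)
  p <- Mod(fft(b16$samples))^2
  rate <- b16$rate_hz
  freqs <- (0:(length(p) - 1)) * rate / length(p)
  half <- freqs <= rate / 2
  expect_gt(sum(p[half & freqs < 1000]), sum(p[half & freqs > 4000]))
  # independent-stream RMS growth ~ sqrt(k)
  b1 <- make_babble(n_talkers = 1, duration_s = 2, seed = 6)
  r16 <- sqrt(mean(b16$samples^2)); r1 <- sqrt(mean(b1$samples^2))
  expect_equal(r16 / r1, 4, tolerance = 1)
  expect_identical(make_babble(2, 0.5, seed = 9)$samples,
                   make_babble(2, 0.5, seed = 9)$samples)
})

test_that("speech-noise mixing hits the requested SNR", {
  ct <- fixture("cons_stream", make_consonant_tokens(seed = 4))
  sp <- ct$wave
  nz <- make_babble(n_talkers = 4, duration_s = length(sp) / sp$rate_hz + 0.1,
                    seed = 8)
  for (snr in c(0, 3, 20)) {
    mx <- mix_at_snr(sp, nz, snr)
    active <- abs(sp$samples) > 0
    s_rms <- sqrt(mean(sp$samples[active]^2))
    n_scaled <- mx$samples - sp$samples
    n_rms <- sqrt(mean(n_scaled[seq_along(sp$samples)]^2))
    expect_equal(20 * log10(s_rms / n_rms), snr, tolerance = 0.1)
  }
  expect_error(mix_at_snr(sp, waveform(numeric(length(sp) + 1))), "silent")
})

test_that("WAV and label round trips preserve the stream", {
  ts <- make_tone_stream(freqs = 1000, levels = c(60, 70), seed = 1)
  f <- tempfile(fileext = ".wav")
  write_wav(ts$wave, f)
  back <- read_wav(f, rate_hz = ts$wave$rate_hz)
  expect_equal(back$samples, ts$wave$samples, tolerance = 1e-6)
  fl <- tempfile(fileext = ".csv")
  write_labels(ts$labels, fl)
  lab <- read.csv(fl)
  expect_equal(nrow(lab), nrow(ts$labels))
  expect_equal(lab$onset_s, ts$labels$onset_s)
})
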