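#' Hearing-loss profile (audiogram threshold shifts)
#'
#' Threshold elevations in dB at the standard audiogram frequencies.
#'
#' @param shift_db nonnegative threshold shifts at `freq_hz`.
#' @param freq_hz audiogram frequencies (default 500-8000 Hz, octave spaced).
#' @return an object of class `hearing_profile`.
#' @export
hearing_profile <- function(shift_db = rep(0, 5),
                            freq_hz = c(500, 1000, 2000, 4000, 8000)) {
  stopifnot(length(shift_db) == length(freq_hz), all(is.finite(shift_db)))
  structure(list(shift_db = shift_db, freq_hz = freq_hz),
            class = "hearing_profile")
}

#' Typical sloping mild-to-moderate sensorineural loss
#' @return a [hearing_profile] with shifts rising from 20 dB at 500 Hz to
#'   60 dB at 8 kHz.
#' @export
sloping_loss_profile <- function() {
  hearing_profile(c(20, 25, 35, 50, 60))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Build a synthetic IC population specification
#'
#' Units have log-spaced characteristic frequencies (CFs) between 500 Hz and
#' 8 kHz, per-unit thresholds and tuning bandwidths, and nonnegative mixing
#' weights onto a small number of shared latent channels. Hearing loss raises
#' each unit's threshold by the audiogram shift interpolated at its CF and
#' broadens its tuning (doubling per 30 dB of shift by default).
#'
#' @param n_units number of units (default 64).
#' @param signal_dim true latent dimensionality (default 6).
#' @param signal_var_fraction target trial-reproducible share of response
#'   variance, in (0, 1) (default 0.4).
#' @param hearing a [hearing_profile] (default: no loss).
#' @param seed integer seed (mixing-weight jitter).
#' @param base_threshold_db normal-hearing unit threshold (default 20 dB SPL).
#' @param tuning_bw_octaves normal-hearing tuning bandwidth (default 0.5).
#' @param broadening_per_30db bandwidth multiplier per 30 dB of threshold
#'   shift (default 2).
#' @return an object of class `population_spec`.
#' @export
make_population <- function(n_units = 64, signal_dim = 6,
                            signal_var_fraction = 0.4,
                            hearing = hearing_profile(), seed = 1,
                            base_threshold_db = 20, tuning_bw_octaves = 0.5,
                            broadening_per_30db = 2) {
  stopifnot(n_units >= signal_dim)
  if (signal_var_fraction <= 0 || signal_var_fraction >= 1)
    stop("signal_var_fraction must be in (0, 1)")
  cf <- 10^seq(log10(500), log10(8000), length.out = n_units)
  shift <- interp_shift(hearing$shift_db, hearing$freq_hz, cf)
  threshold <- base_threshold_db + shift
  bw <- tuning_bw_octaves * broadening_per_30db^(shift / 30)
  latent_cf <- latent_channel_cfs(signal_dim)
  oct_dist <- outer(log2(cf), log2(latent_cf), "-")
  # mixing kernel narrows with latent-channel spacing so densely packed
  # channels keep distinct population embeddings; hearing loss still
  # broadens it through bw
  spacing <- if (signal_dim > 1) 4 / (signal_dim - 1) else 4
  shrink <- min(1, 0.25 * spacing / tuning_bw_octaves)
  mixing <- exp(-(oct_dist / (bw * shrink))^2)
  mixing <- with_seed(substream_seed(seed, "mixing"),
                      mixing * exp(0.5 * matrix(rnorm(n_units * signal_dim),
                                                n_units, signal_dim)))
  # column normalization equalizes each latent channel's total population
  # loading (unit drives are standardized later, so row scale is irrelevant)
  mixing <- sweep(mixing, 2, pmax(sqrt(colSums(mixing^2)),
                                  .Machine$double.eps), "/")
  structure(list(n_units = n_units, signal_dim = signal_dim,
                 signal_var_fraction = signal_var_fraction,
                 cf_hz = cf, threshold_db = threshold,
                 tuning_bw_octaves = bw, mixing = mixing,
                 hearing = hearing, seed = seed,
                 base_threshold_db = base_threshold_db),
            class = "population_spec")
}

latent_channel_cfs <- function(signal_dim) {
  if (signal_dim == 1) return(2000)
  10^seq(log10(500), log10(8000), length.out = signal_dim)
}

# Band envelope of a waveform in a log-symmetric band around cf, averaged
# into time bins of bin_s seconds. Returns the binned envelope amplitude.
binned_band_envelope <- function(w, cf, bw_oct, bin_s) {
  f_lo <- max(cf * 2^(-bw_oct / 2), 30)
  f_hi <- min(cf * 2^(bw_oct / 2), w$rate_hz / 2 * 0.98)
  n <- length(w$samples)
  np <- nextn(n, c(2, 3, 5))       # pad for a fast mixed-radix FFT
  X <- fft(c(w$samples, numeric(np - n)))
  freqs <- (0:(np - 1)) * w$rate_hz / np
  # analytic band signal: keep positive in-band frequencies, doubled
  mask <- as.numeric(freqs >= f_lo & freqs <= f_hi) * 2
  env <- Mod(fft(X * mask, inverse = TRUE) / np)[seq_len(n)]
  bin_len <- bin_s * w$rate_hz
  n_bins <- floor(n / bin_len)
  idx <- floor((seq_len(n) - 1) / bin_len) + 1
  keep <- idx <= n_bins
  as.numeric(tapply(env[keep], idx[keep], mean))
}

#' Ground-truth latent trajectories for a stimulus and population
#'
#' Latent channel *j* is the standardized sigmoid-compressed level of the
#' stimulus in a band centered at the *j*-th log-spaced latent CF, with the
#' population's (possibly broadened) median bandwidth and the population
#' threshold interpolated at that CF. All trials share these latents; they
#' are the trial-invariant signal component. Exposed separately so repeated
#' simulations from the same stimulus can reuse them.
#'
#' @param w a calibrated [waveform].
#' @param pop a `population_spec`.
#' @param bin_s time-bin width in seconds (default 32/24414.0625).
#' @param level_slope_db sigmoid slope of the rate-level function (10 dB).
#' @return matrix `signal_dim` x `n_bins`.
#' @export
population_latents <- function(w, pop, bin_s = 32 / 24414.0625,
                               level_slope_db = 10) {
  stopifnot(inherits(w, "waveform"), inherits(pop, "population_spec"))
  cfs <- latent_channel_cfs(pop$signal_dim)
  bw <- stats::median(pop$tuning_bw_octaves)
  thr <- approx(log2(pop$cf_hz), pop$threshold_db, xout = log2(cfs),
                rule = 2)$y
  lat <- t(vapply(seq_along(cfs), function(j) {
    env <- binned_band_envelope(w, cfs[j], bw, bin_s)
    lev <- w$spl_ref_db + 20 * log10(pmax(env / sqrt(2), 1e-12))
    1 / (1 + exp(-(lev - thr[j]) / level_slope_db))
  }, numeric(floor(length(w$samples) / (bin_s * w$rate_hz)))))
  # standardize each channel over time; channels the stimulus never drives
  # (constant envelope) are left at zero rather than noise-amplified
  mu <- rowMeans(lat)
  sdv <- apply(lat, 1, sd)
  live <- sdv > 1e-8
  lat <- (lat - mu) / pmax(sdv, 1e-12)
  lat[!live, ] <- 0
  if (sum(live) > 1) {
    # ZCA whitening: removes residual inter-band envelope correlation while
    # keeping each channel aligned with its frequency band
    C <- tcrossprod(lat[live, , drop = FALSE]) / (ncol(lat) - 1)
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 1e-6 * e$values[1])
    W <- e$vectors %*% (t(e$vectors) / sqrt(ev))
    lat[live, ] <- W %*% lat[live, , drop = FALSE]
  }
  lat
}

#' Simulate trial-structured spike counts from a synthetic population
#'
#' Unit rates are `softplus(mixing %*% latents + 0.5)`, scaled per unit in
#' closed form so the expected trial-reproducible (signal) share of count
#' variance matches `pop$signal_var_fraction` against the Poisson noise
#' floor. Counts are Poisson, independent across trials and units, with one
#' random substream per (trial, unit).
#'
#' @param w a calibrated [waveform].
#' @param pop a `population_spec`.
#' @param n_trials number of repeated trials (>= 1).
#' @param seed integer seed.
#' @param bin_s time-bin width in seconds.
#' @param latents optional precomputed [population_latents()] matrix.
#' @return an object of class `sim_recording` with `counts`
#'   (trials x units x bins), `true_latents`, `bin_s`, `rates`.
#' @export
simulate_response <- function(w, pop, n_trials = 2, seed = 1,
                              bin_s = 32 / 24414.0625, latents = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (is.null(latents)) latents <- population_latents(w, pop, bin_s)
  stopifnot(nrow(latents) == pop$signal_dim)
  n_bins <- ncol(latents)
  pre <- pop$mixing %*% latents
  pre <- (pre - rowMeans(pre)) / pmax(apply(pre, 1, sd), 1e-12)
  m <- softplus(pre + 0.5)
  f <- pop$signal_var_fraction
  em <- rowMeans(m)
  vm <- apply(m, 1, var)
  ok <- vm > 1e-12
  g <- ifelse(ok, f * em / ((1 - f) * pmax(vm, 1e-12)), 1)
  # equalize the signal power carried by each latent channel's population
  # block (so the generator's dimensionality is expressed isotropically),
  # then rescale globally so the aggregate signal share equals f
  chan <- apply(pop$mixing, 1, which.max)
  s_u <- g^2 * vm                     # per-unit signal variance
  S_j <- tapply(s_u, chan, sum)
  if (length(S_j) == pop$signal_dim && all(S_j > 0)) {
    cj <- mean(S_j) / S_j[as.character(chan)]
    g <- g * sqrt(as.numeric(cj))
  }
  A <- sum(g^2 * vm)
  B <- sum(g * em)
  if (A > 1e-12) g <- g * f * B / ((1 - f) * A)
  rates <- m * g                      # expected counts per bin
  counts <- array(0L, dim = c(n_trials, pop$n_units, n_bins))
  for (tr in seq_len(n_trials)) {
    for (u in seq_len(pop$n_units)) {
      counts[tr, u, ] <- with_seed(
        substream_seed(seed, paste0("trial", tr, "unit", u)),
        rpois(n_bins, rates[u, ]))
    }
  }
  structure(list(counts = counts, true_latents = latents, bin_s = bin_s,
                 rates = rates, pop = pop, seed = seed),
            class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<sim_recording> %d trials x %d units x %d bins (%.4f ms bins)\n",
              d[1], d[2], d[3], x$bin_s * 1000))
  invisible(x)
}

# Biphasic extracellular spike template, ~1.2 ms long, positive peak = 1.
spike_template <- function(rate_hz) {
  t <- seq(0, 0.0012, by = 1 / rate_hz)
  tpl <- sin(2 * pi * 1500 * t) * exp(-((t - 0.0004) / 0.0004)^2)
  tpl / max(tpl)
}

#' Synthesize a raw voltage trace with known spike times
#'
#' Inserts a biphasic spike template (positive peak `spike_amp`) at the given
#' times into band-limited Gaussian noise of known standard deviation.
#' Overlapping templates sum.
#'
#' @param spike_times_s spike times in seconds, within the trace duration.
#' @param noise_sd standard deviation of the background noise.
#' @param rate_hz sampling rate.
#' @param duration_s trace duration (> 0).
#' @param spike_amp spike peak amplitude (same units as `noise_sd`).
#' @param seed integer seed.
#' @return a [waveform] holding the voltage trace.
#' @export
synthesize_raw_trace <- function(spike_times_s, noise_sd, rate_hz = 24414.0625,
                                 duration_s = 1, spike_amp = 10 * noise_sd,
                                 seed = 1) {
  if (duration_s <= 0) stop("trace duration must be positive")
  if (length(spike_times_s) && max(spike_times_s) > duration_s)
    stop("spike times must lie within the trace duration")
  n <- round(duration_s * rate_hz)
  x <- with_seed(substream_seed(seed, "trace_noise"), {
    noise <- rnorm(n)
    bf <- signal::butter(4, c(700, 5000) / (rate_hz / 2), type = "pass")
    noise <- signal::filtfilt(bf, noise)
    noise / sd(noise) * noise_sd
  })
  tpl <- spike_template(rate_hz) * spike_amp
  for (ts in spike_times_s) {
    i0 <- round(ts * rate_hz) + 1
    idx <- i0:min(i0 + length(tpl) - 1, n)
    x[idx] <- x[idx] + tpl[seq_along(idx)]
  }
  waveform(x, rate_hz)
}

#' Simulate an ABR intensity sweep
#'
#' For each intensity, produces a 30 ms median evoked-response window: a
#' windowed tone-burst wavelet whose amplitude follows a sigmoid of
#' (level - true threshold), plus residual noise. A silence window with the
#' same residual-noise level is included for the threshold rule. Amplitudes
#' are calibrated so that at the true threshold the evoked RMS is 2.2x the
#' expected silence RMS.
#'
#' @param freq tone frequency in Hz.
#' @param levels ascending intensities in dB SPL (5 dB grid).
#' @param true_threshold_db ground-truth threshold.
#' @param seed integer seed.
#' @param rate_hz sampling rate.
#' @param residual_sd residual noise SD in the median windows.
#' @return list with `levels`, `responses` (samples x levels), `silence`.
#' @export
simulate_abr_sweep <- function(freq, levels, true_threshold_db, seed = 1,
                               rate_hz = 24414.0625, residual_sd = 0.05) {
  stopifnot(!is.unsorted(levels))
  n <- round(0.030 * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  n_cyc <- round(5 * rate_hz / freq)
  wavelet <- numeric(n)
  i0 <- round(0.005 * rate_hz)
  idx <- i0 + seq_len(min(n_cyc, n - i0))
  tt <- seq_along(idx) / rate_hz
  wavelet[idx] <- sin(2 * pi * freq * tt) *
    (0.42 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx)) +
       0.08 * cos(4 * pi * seq_along(idx) / length(idx)))
  w_rms <- rms(wavelet)
  amp_at_thr <- 2.2 * residual_sd / w_rms
  responses <- with_seed(substream_seed(seed, "abr"), {
    vapply(levels, function(L) {
      a <- 2 * amp_at_thr / (1 + exp(-(L - true_threshold_db) / 2.5)) *
        (L >= true_threshold_db - 15)
      wavelet * a + rnorm(n, sd = residual_sd)
    }, numeric(n))
  })
  silence <- with_seed(substream_seed(seed, "abr_silence"),
                       rnorm(n, sd = residual_sd))
  list(levels = levels, responses = responses, silence = silence)
}
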