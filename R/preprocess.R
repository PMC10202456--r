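#' Robust noise-SD estimate of a filtered trace
#'
#' Median absolute deviation divided by 0.6745, i.e. the MAD scaled to be
#' consistent with the standard deviation for Gaussian noise. Robust to
#' sparse large outliers such as spikes.
#'
#' @param x numeric trace (already bandpass filtered).
#' @return estimated standard deviation.
#' @export
estimate_noise_sd <- function(x) {
  s <- mad(x, constant = 1 / 0.6745)
  if (s == 0) warning("constant trace: noise SD estimate is 0")
  s
}

mua_bandpass <- function(x, rate_hz, band = c(700, 5000), order = 4) {
  bf <- signal::butter(order, band / (rate_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Extract multi-unit activity (MUA) from a raw voltage trace
#'
#' Bandpass filters the trace (700-5000 Hz, 4th-order zero-phase
#' Butterworth), detects positive crossings of 3.5 robust noise SDs,
#' imposes a 1 ms refractory merge, and bins event times into half-open
#' bins anchored at t = 0.
#'
#' @param w a [waveform] holding the raw trace (rate >= 10 kHz).
#' @param bin_s bin width in seconds (default 32/24414.0625, about 1.3 ms).
#' @param threshold_sd detection threshold in noise SDs (default 3.5).
#' @param band,order bandpass cutoffs (Hz) and filter order.
#' @param refractory_s minimum separation between events (default 1 ms).
#' @return list with `counts` (integer vector, one element per bin),
#'   `event_times_s`, `bin_s`, `noise_sd`.
#' @export
extract_mua <- function(w, bin_s = 32 / 24414.0625, threshold_sd = 3.5,
                        band = c(700, 5000), order = 4,
                        refractory_s = 0.001) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate_hz < 2 * band[2]) stop("sampling rate below twice the band top")
  if (length(w$samples) < bin_s * w$rate_hz)
    stop("trace shorter than one bin")
  xf <- mua_bandpass(w$samples, w$rate_hz, band, order)
  sdn <- estimate_noise_sd(xf)
  th <- threshold_sd * sdn
  above <- xf >= th
  cross <- which(above[-1] & !above[-length(above)]) + 1
  if (length(cross) > 1) {
    # sequential merge: an event only survives if far enough from the last
    # *kept* event
    keep <- logical(length(cross)); keep[1] <- TRUE
    last <- cross[1]
    for (i in seq_along(cross)[-1]) {
      if ((cross[i] - last) / w$rate_hz >= refractory_s) {
        keep[i] <- TRUE; last <- cross[i]
      } else keep[i] <- FALSE
    }
    cross <- cross[keep]
  }
  times <- (cross - 1) / w$rate_hz
  n_bins <- floor(length(w$samples) / (bin_s * w$rate_hz))
  counts <- bin_events(times, bin_s, n_bins)
  list(counts = counts, event_times_s = times, bin_s = bin_s, noise_sd = sdn)
}

# Half-open bins [k*bin_s, (k+1)*bin_s); events on an edge go to the later bin.
bin_events <- function(times_s, bin_s, n_bins) {
  idx <- floor(times_s / bin_s) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  as.integer(tabulate(idx, nbins = n_bins))
}

#' Select units by cross-trial signal correlation
#'
#' A unit is retained when the correlation between its responses on two
#' repeats of identical stimulation reaches `min_sig_corr`. Zero-variance
#' units are excluded.
#'
#' @param rec1,rec2 units x bins count matrices from two repeats.
#' @param min_sig_corr retention threshold (default 0.2).
#' @return logical vector, one element per unit.
#' @export
select_units <- function(rec1, rec2, min_sig_corr = 0.2) {
  stopifnot(all(dim(rec1) == dim(rec2)))
  vapply(seq_len(nrow(rec1)), function(u) {
    if (sd(rec1[u, ]) == 0 || sd(rec2[u, ]) == 0) return(FALSE)
    cor(rec1[u, ], rec2[u, ]) >= min_sig_corr
  }, logical(1))
}

#' ABR threshold from an intensity sweep
#'
#' Returns the lowest intensity at which the RMS of the median evoked
#' response exceeds twice the RMS of the median activity recorded in the
#' absence of sound. `Inf` if no level qualifies.
#'
#' @param levels ascending intensities in dB SPL.
#' @param responses samples x levels matrix of median response windows.
#' @param silence median silence window (same residual-noise statistics).
#' @return threshold in dB SPL, or `Inf`.
#' @export
abr_threshold <- function(levels, responses, silence) {
  if (missing(silence) || is.null(silence))
    stop("a silence recording is required for the threshold rule")
  stopifnot(!is.unsorted(levels), ncol(responses) == length(levels))
  ref <- rms(silence)
  hit <- which(apply(responses, 2, rms) > 2 * ref)
  if (length(hit) == 0) return(Inf)
  levels[min(hit)]
}
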