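---
title: "Models and methods behind icdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`icdyn` is a pipeline for studying how sensorineural hearing loss distorts
the low-dimensional, trial-reproducible component of auditory midbrain
population activity. This vignette explains the models the package
implements, the assumptions behind them, the tunable parameters and their
defaults, and the design choices made where the design was genuinely open.
It states no empirical result that the package's tests and acceptance script
do not themselves compute.

## The signal/noise decomposition and the signal manifold

Population activity is represented as a units x time-bins count matrix `R`
with ~1.31 ms bins (exactly 32 samples at the 24414.0625 Hz audio rate, so
neural bins and audio samples stay commensurate). Given two repeats of
identical stimulation, the *signal* of a unit is the component reproduced
across repeats and the *noise* is the residual. `signal_noise_stats()`
estimates the per-unit signal variance as the cross-trial covariance, total
variance as the average single-trial variance, and noise as their
difference; the decomposition is additive by construction, and pairwise
covariances are normalized by the total variances so signal and noise
correlations also add to the total correlation.

`fit_pcs()` performs PCA on a training matrix after removing each unit's
mean. Projecting a test repeat onto the leading `D` components gives the
latent dynamics `X = Z R`; reconstructing and comparing against the same
repeat yields *total* variance explained, against the other repeat *signal*
variance explained (only trial-reproducible structure survives this
comparison). Two statistics are offered:

* `"normcov"` - the normalized covariance between reconstruction and data
  (a correlation over all matrix entries), the literal form of the
  variance-explained ratio used in the field;
* `"r2"` - conventional 1 - SSE/SST.

`signal_dimensionality()` returns the smallest `D` whose signal-variance
curve reaches 95% of its plateau. For dimensionality *recovery* studies we
recommend (and our acceptance suite uses) the `"r2"` curve: when a generator
distributes signal equally over `d` latent dimensions, the correlation-form
curve rises like `sqrt(D/d)`, so the 95% rule sits at `sqrt((d-1)/d)` - a
margin of 0.0013 at `d = 10` - and exact recovery becomes numerically
knife-edge for `d >= 9` no matter how much data is collected. The R-squared
curve rises like `D/d` and leaves a 5% margin. Both statistics are exposed;
the choice matters only for reading off dimensionalities near 10.

`cross_animal_similarity()` regresses one animal's latent trajectories onto
another's (OLS with intercept, pooled over dimensions, in-sample by default
with an optional split), quantifying how much of one animal's signal
dynamics is linearly predictable from another's.

## The synthetic population generator

`make_population()` + `simulate_response()` produce trial-structured counts
with the statistical structure the analyses assume, plus recorded ground
truth for parameter-recovery tests. The generative model:

1. *Latent channels.* `signal_dim` log-spaced center frequencies between
   500 Hz and 8 kHz. Each channel is the band envelope of the stimulus
   (frequency-domain bandpass, analytic envelope, averaged into bins),
   converted to dB, passed through a sigmoid rate-level function (10 dB
   slope) centered on the population threshold at that frequency, then
   standardized. Channels the stimulus never drives are left at zero.
   Residual inter-band correlation is removed by ZCA whitening, which is the
   orthogonalization closest to the original channels, so channel *j* stays
   aligned with its frequency band. All trials share these latents - the
   signal is trial-invariant by construction.
2. *Mixing.* Each unit weights the latent channels with a nonnegative
   Gaussian tuning kernel centered on its characteristic frequency, jittered
   multiplicatively (log-normal, sd 0.5) and column-normalized. The kernel
   narrows with the latent-channel spacing so that densely packed channels
   keep distinct population embeddings; without this, neighboring channels
   blur together and the generator's own signal spectrum would be
   non-isotropic, i.e. no estimator could recover the nominal dimension.
3. *Rates and counts.* Unit drives are standardized, passed through a
   softplus (smooth, strictly positive - any smooth nonnegative link
   satisfies the analyses' assumptions), and scaled in closed form so that
   (a) each latent channel's population block carries equal signal power and
   (b) the population-aggregate trial-reproducible share of count variance
   equals `signal_var_fraction` against the Poisson noise floor
   (`g = f/(1-f) * E[m]/Var[m]`, then one global rescale). Counts are
   Poisson, independent across trials and units, drawn from one random
   substream per (trial, unit) so changing the unit count never perturbs
   other units.

Hearing loss enters through a `hearing_profile` (threshold shifts at
500-8000 Hz): unit thresholds rise by the shift interpolated at their CF,
and tuning bandwidth multiplies by 2 per 30 dB of shift (the broadening
magnitude is a free config parameter; physiology motivates the direction,
not a precise value).

What the generator emulates: a low-dimensional trial-reproducible signal
shared across units, independent Poisson trial noise, frequency/intensity
tuning, elevated thresholds and broadened tuning under sloping loss. What it
does not: adaptation and other history dependence, correlated (shared) trial
noise, inhibitory sidebands, or the specific clustering phenomenology of
real midbrain populations. Tests passing on this generator therefore
establish the *estimators'* correctness and calibration, not claims about
real tissue.

`make_multiband_scene()` complements the generator for recovery studies: a
sum of band-noise streams at the latent center frequencies with independent
slowly varying envelopes spanning an 80 dB range, so every latent channel is
driven independently through its informative (non-saturated) range.
Dimensionality recovery uses 64 units, a 0.4 signal share, and ~50k bins
(66 s) per run.

## Raw traces, MUA, and ABR thresholds

`synthesize_raw_trace()` inserts a biphasic ~1.2 ms spike template into
700-5000 Hz band-limited Gaussian noise of known SD. `extract_mua()`
bandpass-filters (4th-order zero-phase Butterworth; the cutoff family and
order are config knobs since only the band edges are standard), estimates
the noise SD robustly as MAD/0.6745, detects positive crossings of 3.5 SDs,
merges events within 1 ms (one spike waveform can cross twice; the
refractory rule prevents double counts), and bins events into half-open bins
anchored at t = 0 (edge events go to the later bin). At a 3.5 SD threshold,
Gaussian upcrossing theory predicts a few false events per second in this
band; the detector's false-positive rate is tested against that Rice-formula
oracle rather than against zero.

`simulate_abr_sweep()` produces 30 ms median-response windows whose evoked
amplitude is a sigmoid of level re threshold, calibrated so the evoked RMS
at threshold is 2.2x the residual-noise RMS; `abr_threshold()` applies the
rule "lowest level whose median-response RMS exceeds twice the silence RMS"
(sentinel `Inf` when nothing qualifies). Recovery is within one 5 dB step
of the generator's truth.

## The WDRC hearing-aid simulator

`wdrc_process()` implements a 10-channel wide-dynamic-range compressor:
crossovers at 200/500/1000/1750/2750/4000/5500/7000/8500 Hz, per-channel
knees (45, 43, 40, 38, 35, 33, 28, 30, 36, 44 dB SPL), linear gain below the
knee, and 1 dB of output per `ratio` dB of input above it. Design choices:

* Band split: zero-phase complementary frequency-domain masks that assign
  every FFT bin to exactly one channel, so the analysis-synthesis chain is
  exactly flat (verified by test). No filter family is standard here; exact
  complementarity removes one source of arbitrariness.
* Level estimation: a one-pole follower on instantaneous *power* with
  separate attack (5 ms) and release (40 ms) coefficients
  `alpha = exp(-1/(tau * rate))`. Power-domain tracking makes the settled
  estimate exact for steady tones, so static input-output curves hit the
  analytic compressor curve; at sharp transients an RMS tracker and a peak
  tracker differ, and this implementation is on the RMS side.
* `fit_from_audiogram()` maps threshold shifts to gains by the half-gain
  rule capped at 30 dB and to ratios by `1 + shift/40` capped at 2.5,
  deterministic; a typical sloping mild-to-moderate loss yields ~10 dB of
  low-frequency and ~30 dB of high-frequency gain. Clinical prescription
  software is out of scope; gains/ratios are ordinary config inputs.

## The convolutional encoder

`encoder_init()` builds the sound-to-activity model: (1) a bank of sinc
bandpass filters (length 32; learnable center frequency and bandwidth;
mel-spaced initialization 50 Hz-12 kHz with third-octave bandwidths) under
symmetric-log activations `sign(x) log(1+|x|)`; (2) five stride-2
convolutions (kernel 32, PReLU with one learnable slope per channel,
"same" padding) for a cumulative decimation of 32; (3) a stride-1 bottleneck
convolution of dimensionality `Db`; (4) a linear per-unit readout under an
exponential, whose output is the expected count per 1.31 ms bin. A nominal
decimation "factor of 5" is sometimes quoted for this architecture; the
arithmetic (24414.0625 / 762.9395 = 32 = 2^5) shows five stride-2 layers,
i.e. a factor of 32 with five halvings, which is what is implemented. An
8192-sample frame maps to 256 bins, and cropping 32 bins at each end (edge
effects) leaves 192.

Training is Poisson regression (`sum(Rhat - R log Rhat)`) with Adam,
single-precision-scale learning rates, and seeds fixing initialization and
batch order; the gradient is normalized per bin and batch so learning rates
transfer across frame counts. The readout bias warm-starts at each unit's
log mean count (the Poisson MLE for a constant rate). Backpropagation -
including the analytic gradient of the sinc kernels with respect to center
frequency and bandwidth - is verified against numerical differentiation in
the test suite. The LN baseline keeps stages 1 and 4 with a single stride-1
convolution between them; its audio-rate output is average-pooled by 32 so
both models share the output contract.

Scaled problem sizes: the package's tests train reduced-width models
(6-8 sinc filters, 12-16 conv filters, bottleneck 4) on 5 minutes of
synthetic data for 2 epochs at learning rate 1e-3 - enough for held-out
loss to fall and for the deep model to separate from the LN baseline on
data from the nonlinear generator. These sizes are the package's chosen
study scale for a desk-scale replication; the architecture defaults keep
the full-scale values. Output-bin alignment uses the left edge of each
stride window; shift-equivariance (32 samples in, 1 bin over) is tested.
Whether PReLU slopes are shared per layer or per channel is an open choice;
the default is per-channel.

## Comparing latent dynamics

*RSA.* `sound_trajectories()` cuts dynamics into per-sound segments,
truncates to the common length, flattens (channels' time courses
concatenated), and averages instances that share a sound identity (for
consonants: across talkers). `compute_rdm()` forms 1 - correlation between
sound pairs; `rdm_similarity()` correlates vectorized upper triangles;
`best_intensity()` maximizes that similarity over presentation levels with
ties broken toward the lower level (removing pure audibility effects).

*CCA.* `cca_align()` computes canonical components via QR factorization and
SVD of the centered dynamics, matching the classical algorithm (verified
against `stats::cancor`). `cca_similarity()` is the weighted sum
`sum_d rho(U_d, V_d) * (rho(Xhat_d, X)^2 + rho(Yhat_d, Y)^2) / 2`. The
rank-1 reconstruction `Xhat_d` is the regression of the dynamics on the
*canonical variate* `U_d` (projection in time), not on the coefficient
vector `a_d`: with the variate reading the weights of a full-rank
self-comparison sum to exactly 1 - the row norms of `A^-1` normalized - so
`cca_similarity(X, X) = 1` holds identically, whereas projecting onto the
oblique coefficient vectors does not sum to 1 for correlated channels. The
statistic is bounded by 1 and symmetric. `mcca_align()` handles three or
more datasets by per-dataset PCA whitening (relative eigenvalue floor
1e-8), concatenation, and a joint PCA; joint eigenvalues near the number of
datasets indicate components shared by all.

*Decoding.* `decode_consonants()` trains one-vs-one linear SVMs
(`e1071::svm`, cost 1, no feature scaling) over all class pairs with
max-wins voting and stratified tenfold cross-validation. With 22 balanced
classes and shuffled labels, accuracy sits at the 1/22 ~ 4.5% chance level,
which the acceptance script recomputes.

*Other probes.* `envelope_tracking_cv()` summarizes temporal envelope
following as SD/mean of condition-mean activations (for a sinusoidally
modulated positive signal the closed form is `depth/sqrt(2)`);
`compute_fra()` grids mean activations over tone frequency x intensity;
`masking_correlation_grid()` correlates dynamics for a narrowband target
with and without a masker across center-frequency grids.

## Numerical choices and degenerate inputs

* Correlations are Pearson on mean-centered data; constant vectors are
  excluded with a warning (zero-variance units, constant RDMs).
* FFT-based operations pad to fast lengths and truncate, so awkward
  sample counts do not hit the mixed-radix worst case.
* Cross-trial covariance estimators use the unbiased (n-1) normalization.
* All-zero time bins are retained in all manifold statistics.
* Every generator draws from named substreams of one root seed
  (`stimuli`, `population`, `trial x unit`, `batch_order`, `folds`), so
  configurations are exactly reproducible and components can be regenerated
  independently.
* Rank-deficient inputs to PCA/CCA/MCCA reduce the component count and are
  flagged rather than erroring.

## Known limitations

* The synthetic generator's noise is private to each unit; real recordings
  contain shared (noise-correlated) variability that would lower the
  effective SNR of manifold estimates.
* The consonant tokens are parametric class-structured stand-ins (vowel-like
  harmonic / plosive transient / fricative noise with talker jitter), not
  recorded speech; decoding results calibrate the decoder, they do not
  measure speech intelligibility.
* The WDRC simulator omits feedback cancellation, noise reduction, and
  binaural linkage, and its level estimator is RMS-like at transients.
* Encoder training at full scale (48/128-filter architecture, hours of
  audio) is supported by the code but not exercised by the tests, which use
  the scaled-down sizes above.
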