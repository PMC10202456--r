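# icdyn

Signal manifolds and latent dynamics of auditory midbrain populations.

`icdyn` is an R package for studying how sensorineural hearing loss distorts
the *neural signal* — the trial-reproducible, stimulus-locked component of
population activity in the inferior colliculus — once that signal is viewed
in the low-dimensional subspace (the *signal manifold*) where it lives. It
is aimed at auditory and computational neuroscientists who want a tested,
desk-scale implementation of the full analysis chain, from calibrated
stimulus synthesis to latent-dynamics comparison, with a synthetic
population generator providing ground truth for every estimator.

## What's inside

**Signal/noise decomposition and manifold identification.** Given two
repeats of identical stimulation, a unit's signal variance is the
cross-trial covariance, its total variance the average single-trial
variance, and noise the difference — additive by construction. PCA on a
training matrix `R` (units × 1.31 ms bins, means removed) gives components
`Z`; latent dynamics are `X = Z R`, and reconstructions `R̂ = Zᵀ X` measured
against the same repeat (total variance explained) or the other repeat
(signal variance explained) yield the curves whose 95%-of-plateau point
defines the signal-manifold dimensionality. Similarity of dynamics across
animals is the variance explained by the regression `Y = Xβ + ε`.

**A bottlenecked convolutional encoder.** Sound → sinc filterbank
(learnable center frequencies and bandwidths, symmetric-log activations) →
five stride-2 convolutions (PReLU) → a `Db`-channel bottleneck → linear +
exponential per-unit readout, trained as Poisson regression
`Σ (R̂ − R log R̂)` with Adam. An 8192-sample frame at 24414.0625 Hz becomes
192 neural bins at 762.9395 Hz. Backpropagation (including the sinc
parameter gradients) is implemented in the package with RcppArmadillo
kernels and verified against numerical differentiation; an LN baseline and
frozen-encoder transfer learning are included.

**Latent-dynamics comparison.** Representational dissimilarity matrices
(1 − correlation between per-sound trajectories), the weighted canonical-
correlation similarity `Σ_d ρ(U_d,V_d)·(ρ(X̂_d,X)² + ρ(Ŷ_d,Y)²)/2`, multiway
CCA for three or more datasets, frequency response areas, envelope-tracking
coefficients of variation, masking grids, and one-vs-one max-wins SVM
consonant decoding with tenfold cross-validation (chance = 1/22 ≈ 4.5%).

**Stimuli and hearing-aid simulation.** Calibrated tone, SAM-noise,
narrowband target/masker, synthetic consonant, and multi-talker babble
generators (RMS 1 ↔ 94 dB SPL), and a 10-channel wide-dynamic-range
compressor (5 ms attack / 40 ms release; above the knee, output rises 1 dB
per `ratio` dB of input) with audiogram-based fitting.

**Synthetic midbrain populations.** Trial-structured Poisson counts driven
by a low-dimensional latent signal derived from band envelopes, with
per-unit frequency tuning, threshold elevation and tuning broadening under
hearing loss, and a closed-form guarantee that the trial-reproducible share
of count variance matches its target (0.4 by default).

## Worked example

```r
library(icdyn)

# A multiband scene whose bands fluctuate independently, at 60 dB SPL
w   <- set_level(make_multiband_scene(n_bands = 4, duration_s = 30, seed = 1), 60)

# 32 synthetic units, 4 true latent dimensions, 40% signal variance
pop <- make_population(n_units = 32, signal_dim = 4,
                       signal_var_fraction = 0.4, seed = 1)
rec <- simulate_response(w, pop, n_trials = 3, seed = 2)

st <- signal_noise_stats(rec$counts[2, , ], rec$counts[3, , ])
sum(st$signal_var) / sum(st$total_var)
#> aggregate signal share: 0.40

basis  <- fit_pcs(rec$counts[1, , ])
curves <- variance_explained_curves(rec$counts[2, , ], rec$counts[3, , ],
                                    basis, 1:8, statistic = "r2")
round(curves$signal_ve, 3)
#> [1] 0.129 0.212 0.278 0.345 0.323 0.300 0.279 0.255
signal_dimensionality(curves$signal_ve)
#> [1] 4

io <- static_io_curve(wdrc_config(), channel = 8, input_levels = c(45, 50))
diff(io$input_db) / diff(io$output_db)
#> dB in per dB out above the knee: 2.49
```

The signal share of count variance comes out at its 0.40 target; the
signal-variance curve peaks at the generator's 4 latent dimensions, which
the 95% rule recovers; and a compressor channel configured with ratio 2.5
needs 2.49 dB of input per decibel of output once the level estimator has
settled.

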