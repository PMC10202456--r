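# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, force(builder), envir = .fx)
  .fx[[name]]
}

# Small paired-repeat recording with known per-unit rates (units x bins).
toy_repeats <- function(n_units = 8, n_bins = 4000, seed = 42) {
  set.seed(seed)
  latents <- matrix(rnorm(3 * n_bins), 3)
  mix <- matrix(abs(rnorm(n_units * 3)), n_units)
  pre <- mix %*% latents
  pre <- (pre - rowMeans(pre)) / apply(pre, 1, sd)
  rates <- exp(0.6 * pre + 0.3)
  r1 <- matrix(rpois(length(rates), rates), n_units)
  r2 <- matrix(rpois(length(rates), rates), n_units)
  list(rates = rates, r1 = r1, r2 = r2, latents = latents)
}

# Latent dynamics with controlled structure (rows = channels).
toy_dynamics <- function(D = 3, T_ = 500, seed = 7) {
  set.seed(seed)
  matrix(rnorm(D * T_), D) %*% diag(seq(2, 1, length.out = D)) +
    0 # scaled rows
}

# A tiny trained-ish encoder spec used across encoder tests.
tiny_spec <- function(n_units = 4) {
  encoder_spec(n_units = n_units, n_sinc = 6, sinc_len = 16,
               conv_filters = 8, conv_layers = 5, conv_kernel = 8,
               bottleneck = 3, bottleneck_kernel = 8)
}
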