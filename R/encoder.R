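#' Symmetric logarithm
#'
#' `sign(x) * log(1 + |x|)`: odd, monotone, compressive. Used after the sinc
#' front end of the encoder.
#'
#' @param x numeric.
#' @return transformed values.
#' @export
symmetric_log <- function(x) sign(x) * log1p(abs(x))

symmetric_log_grad <- function(x) 1 / (1 + abs(x))

#' Poisson regression loss
#'
#' `sum(Rhat - R * log(Rhat))` over all units and time bins: the negative
#' Poisson log-likelihood up to a term not involving the prediction.
#'
#' @param Rhat predicted expected counts (strictly positive).
#' @param R observed counts (nonnegative).
#' @return scalar loss.
#' @export
poisson_loss <- function(Rhat, R) {
  stopifnot(all(dim(Rhat) == dim(R) | is.null(dim(Rhat))))
  if (any(Rhat <= 0)) stop("predictions must be strictly positive")
  if (any(R < 0)) stop("counts must be nonnegative")
  sum(Rhat - R * log(Rhat))
}

#' Encoder architecture specification
#'
#' Four stages: (1) a bank of sinc bandpass filters with learnable center
#' frequency and bandwidth, followed by symmetric-log activations; (2) a
#' stack of stride-2 1-D convolutions with PReLU activations (cumulative
#' stride 32); (3) a stride-1 bottleneck convolution with PReLU; (4) a
#' linear per-unit readout with exponential activations. Defaults follow the
#' full-scale model (48 sinc filters, five 128-filter layers, kernel 32);
#' smaller values give scaled-down models with the same shape contract.
#'
#' @param n_units number of output units (readout rows).
#' @param n_sinc number of sinc filters (default 48).
#' @param sinc_len sinc kernel length in samples (default 32).
#' @param conv_filters filters per stacked conv layer (default 128).
#' @param conv_layers number of stride-2 layers (default 5; cumulative
#'   stride must stay 32).
#' @param conv_kernel stacked-layer kernel length (default 32).
#' @param bottleneck bottleneck dimensionality Db (default 8).
#' @param bottleneck_kernel bottleneck kernel length (default 32).
#' @param rate_hz audio sampling rate.
#' @return an `encoder_spec` object.
#' @export
encoder_spec <- function(n_units, n_sinc = 48, sinc_len = 32,
                         conv_filters = 128, conv_layers = 5,
                         conv_kernel = 32, bottleneck = 8,
                         bottleneck_kernel = 32, rate_hz = 24414.0625) {
  stopifnot(conv_layers >= 1, n_units >= 1)
  structure(list(n_units = n_units, n_sinc = n_sinc, sinc_len = sinc_len,
                 conv_filters = conv_filters, conv_layers = conv_layers,
                 conv_kernel = conv_kernel, bottleneck = bottleneck,
                 bottleneck_kernel = bottleneck_kernel, rate_hz = rate_hz,
                 decimation = 2^conv_layers),
            class = "encoder_spec")
}

#' Training configuration
#'
#' @param frame_in input frame length in samples (default 8192; must be
#'   divisible by the encoder decimation factor).
#' @param crop output bins removed at each frame end (default 32).
#' @param batch batch size (default 64).
#' @param epochs training epochs (default 10).
#' @param lr Adam learning rate (default 1e-4).
#' @param seed integer seed (initialization and batch order).
#' @return a `train_config` object.
#' @export
train_config <- function(frame_in = 8192, crop = 32, batch = 64, epochs = 10,
                         lr = 1e-4, seed = 1) {
  structure(list(frame_in = frame_in, crop = crop, batch = batch,
                 epochs = epochs, lr = lr, seed = seed),
            class = "train_config")
}

#' Output frame geometry of the encoder
#'
#' Five stride-2 convolutions decimate by 32, and cropping removes `crop`
#' bins at each end: an 8192-sample frame at 24414.0625 Hz becomes 192
#' neural-activity bins at 762.9395 Hz.
#'
#' @param cfg a [train_config()].
#' @param rate_hz audio sampling rate.
#' @param decimation cumulative stride (default 32).
#' @return list with `out_rate_hz` and `out_len`.
#' @export
frame_geometry <- function(cfg = train_config(), rate_hz = 24414.0625,
                           decimation = 32) {
  if (cfg$frame_in %% decimation != 0)
    stop("frame length must be divisible by the decimation factor")
  list(out_rate_hz = rate_hz / decimation,
       out_len = cfg$frame_in / decimation - 2 * cfg$crop)
}

mel <- function(f) 2595 * log10(1 + f / 700)
mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

# Build sinc kernels and their gradients wrt the (center, band) parameters.
# Kernels are length-L bandpass filters (difference of two windowed sincs)
# at half-integer taps, Hamming windowed.
sinc_kernels <- function(fc, bw, L, rate_hz, grad = FALSE) {
  tn <- (0:(L - 1)) - (L - 1) / 2            # half-integers, never 0
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  f1 <- pmax(abs(fc) - abs(bw) / 2, 1)
  f2 <- pmin(abs(fc) + abs(bw) / 2, 0.495 * rate_hz)
  n1 <- f1 / rate_hz; n2 <- f2 / rate_hz
  W <- matrix(0, length(fc), L)
  for (i in seq_along(fc)) {
    W[i, ] <- (sin(2 * pi * n2[i] * tn) - sin(2 * pi * n1[i] * tn)) /
      (pi * tn) * ham
  }
  if (!grad) return(list(W = W))
  dW_dn1 <- matrix(0, length(fc), L); dW_dn2 <- matrix(0, length(fc), L)
  for (i in seq_along(fc)) {
    dW_dn2[i, ] <- 2 * cos(2 * pi * n2[i] * tn) * ham
    dW_dn1[i, ] <- -2 * cos(2 * pi * n1[i] * tn) * ham
  }
  # chain to (fc, bw) through the clamps (zero gradient when clamped)
  g1 <- as.numeric(abs(fc) - abs(bw) / 2 > 1)
  g2 <- as.numeric(abs(fc) + abs(bw) / 2 < 0.495 * rate_hz)
  list(W = W,
       dW_dfc = (dW_dn1 * (g1 * sign(fc)) + dW_dn2 * (g2 * sign(fc))) / rate_hz,
       dW_dbw = (dW_dn1 * (-g1 * sign(bw) / 2) +
                   dW_dn2 * (g2 * sign(bw) / 2)) / rate_hz)
}

same_pad <- function(L, K, stride) {
  Lout <- ceiling(L / stride)
  tot <- max((Lout - 1) * stride + K - L, 0)
  c(tot %/% 2, tot - tot %/% 2)
}

conv_fwd <- function(X, W, K, stride) {
  p <- same_pad(dim(X)[2], K, stride)
  cpp_conv1d_fwd(X, W, K, stride, p[1], p[2])
}

conv_bwd <- function(X, W, dY, K, stride) {
  p <- same_pad(dim(X)[2], K, stride)
  cpp_conv1d_bwd(X, W, dY, K, stride, p[1], p[2])
}

prelu_fwd <- function(Y, a) {
  pos <- Y > 0
  Y * pos + (a[slice.index(Y, 1)] * Y) * !pos
}

prelu_bwd <- function(Y, a, dOut) {
  pos <- Y > 0
  dY <- dOut * pos + dOut * a[slice.index(Y, 1)] * !pos
  da_full <- dOut * Y * !pos
  da <- rowSums(matrix(da_full, nrow = dim(Y)[1]))
  list(dY = dY, da = da)
}

#' Initialize an encoder model
#'
#' Sinc center frequencies are mel-spaced between 50 Hz and ~12 kHz with
#' bandwidths of a third of an octave; conv weights use He initialization;
#' PReLU slopes start at 0.25 (one learnable slope per channel); readout
#' weights start small with bias giving an initial expected count of
#' `init_rate` per bin.
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed.
#' @param init_rate initial expected count per bin (default 0.1).
#' @return an `encoder_model` object.
#' @export
encoder_init <- function(spec, seed = 1, init_rate = 0.1) {
  stopifnot(inherits(spec, "encoder_spec"))
  with_seed(substream_seed(seed, "encoder_init"), {
    fc <- mel_inv(seq(mel(50), mel(min(12000, 0.45 * spec$rate_hz)),
                      length.out = spec$n_sinc))
    bw <- fc * (2^(1 / 6) - 2^(-1 / 6))         # ~1/3 octave
    params <- list(sinc_fc = fc, sinc_bw = bw)
    cin <- spec$n_sinc
    for (l in seq_len(spec$conv_layers)) {
      params[[paste0("W", l)]] <-
        matrix(rnorm(spec$conv_filters * cin * spec$conv_kernel,
                     sd = sqrt(2 / (cin * spec$conv_kernel))),
               spec$conv_filters, cin * spec$conv_kernel)
      params[[paste0("b", l)]] <- numeric(spec$conv_filters)
      params[[paste0("a", l)]] <- rep(0.25, spec$conv_filters)
      cin <- spec$conv_filters
    }
    params$Wb <- matrix(rnorm(spec$bottleneck * cin * spec$bottleneck_kernel,
                              sd = sqrt(2 / (cin * spec$bottleneck_kernel))),
                        spec$bottleneck, cin * spec$bottleneck_kernel)
    params$bb <- numeric(spec$bottleneck)
    params$ab <- rep(0.25, spec$bottleneck)
    params$Wr <- matrix(rnorm(spec$n_units * spec$bottleneck, sd = 0.01),
                        spec$n_units, spec$bottleneck)
    params$br <- rep(log(init_rate), spec$n_units)
    structure(list(spec = spec, params = params, kind = "deep"),
              class = "encoder_model")
  })
}

#' Number of learnable parameters in a model
#' @param model an `encoder_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Build a linear-nonlinear (LN) baseline model
#'
#' Same sinc front end and exponential readout as the deep encoder, with a
#' single stride-1 convolutional layer (128 filters of length 256 by
#' default) in between. The audio-rate output is average-pooled by the
#' deep model's decimation factor so both models share the same output
#' shape.
#'
#' @param spec an [encoder_spec()]; `conv_filters` and `ln_kernel` set the
#'   middle layer.
#' @param ln_kernel middle-layer kernel length (default 256).
#' @param seed integer seed.
#' @param init_rate initial expected count per bin.
#' @return an `encoder_model` with `kind = "ln"`.
#' @export
build_ln_baseline <- function(spec, ln_kernel = 256, seed = 1,
                              init_rate = 0.1) {
  stopifnot(inherits(spec, "encoder_spec"))
  with_seed(substream_seed(seed, "ln_init"), {
    fc <- mel_inv(seq(mel(50), mel(min(12000, 0.45 * spec$rate_hz)),
                      length.out = spec$n_sinc))
    bw <- fc * (2^(1 / 6) - 2^(-1 / 6))
    params <- list(sinc_fc = fc, sinc_bw = bw)
    params$W1 <- matrix(rnorm(spec$conv_filters * spec$n_sinc * ln_kernel,
                              sd = sqrt(2 / (spec$n_sinc * ln_kernel))),
                        spec$conv_filters, spec$n_sinc * ln_kernel)
    params$b1 <- numeric(spec$conv_filters)
    params$a1 <- rep(0.25, spec$conv_filters)
    params$Wr <- matrix(rnorm(spec$n_units * spec$conv_filters, sd = 0.01),
                        spec$n_units, spec$conv_filters)
    params$br <- rep(log(init_rate), spec$n_units)
    structure(list(spec = spec, params = params, kind = "ln",
                   ln_kernel = ln_kernel),
              class = "encoder_model")
  })
}

avg_pool <- function(Y, factor) {
  d <- dim(Y)
  stopifnot(d[2] %% factor == 0)
  m <- array(Y, c(d[1], factor, d[2] / factor, d[3]))
  out <- aperm(m, c(2, 1, 3, 4))
  array(colMeans(out), c(d[1], d[2] / factor, d[3]))
}

avg_pool_bwd <- function(dOut, factor) {
  d <- dim(dOut)
  big <- array(0, c(d[1], factor, d[2], d[3]))
  for (k in seq_len(factor)) big[, k, , ] <- dOut / factor
  array(big, c(d[1], factor * d[2], d[3]))
}

# Forward pass. X: cube (1, L, B). Returns list with Rhat (and bottleneck
# activations); when cache=TRUE, intermediate tensors for backprop.
encoder_forward <- function(model, X, crop = 0, cache = FALSE,
                            upto = c("readout", "bottleneck")) {
  upto <- match.arg(upto)
  spec <- model$spec; p <- model$params
  sk <- sinc_kernels(p$sinc_fc, p$sinc_bw, spec$sinc_len, spec$rate_hz)
  S <- conv_fwd(X, sk$W, spec$sinc_len, 1L)
  A <- symmetric_log(S)
  cc <- list(X = X, S = S, A = A)
  if (model$kind == "deep") {
    inp <- A
    for (l in seq_len(spec$conv_layers)) {
      pre <- conv_fwd(inp, p[[paste0("W", l)]], spec$conv_kernel, 2L) +
        p[[paste0("b", l)]]
      out <- prelu_fwd(pre, p[[paste0("a", l)]])
      if (cache) { cc[[paste0("in", l)]] <- inp; cc[[paste0("pre", l)]] <- pre }
      inp <- out
    }
    preb <- conv_fwd(inp, p$Wb, spec$bottleneck_kernel, 1L) + p$bb
    Bact <- prelu_fwd(preb, p$ab)
    if (cache) { cc$inb <- inp; cc$preb <- preb }
  } else {
    pre1 <- conv_fwd(A, p$W1, model$ln_kernel, 1L) + p$b1
    out1 <- prelu_fwd(pre1, p$a1)
    Bact <- avg_pool(out1, spec$decimation)
    if (cache) { cc$pre1 <- pre1 }
  }
  if (crop > 0) {
    keep <- (crop + 1):(dim(Bact)[2] - crop)
    Bc <- Bact[, keep, , drop = FALSE]
  } else Bc <- Bact
  if (upto == "bottleneck")
    return(if (cache) c(list(B = Bc), cc) else list(B = Bc))
  d <- dim(Bc)
  Z <- p$Wr %*% matrix(Bc, d[1], d[2] * d[3]) + p$br
  Rhat <- array(exp(Z), c(nrow(p$Wr), d[2], d[3]))
  if (cache) c(list(Rhat = Rhat, B = Bc, crop = crop), cc)
  else list(Rhat = Rhat, B = Bc)
}

# Backward pass: gradient of mean-normalized Poisson loss wrt all params.
# dZ (readout preactivation grad) = (Rhat - R) / (T*B).
encoder_backward <- function(model, fw, R) {
  spec <- model$spec; p <- model$params
  d <- dim(fw$Rhat)
  scale <- 1 / (d[2] * d[3])
  dZ <- (fw$Rhat - R) * scale
  dZm <- matrix(dZ, d[1], d[2] * d[3])
  Bm <- matrix(fw$B, dim(fw$B)[1], d[2] * d[3])
  g <- list(Wr = dZm %*% t(Bm), br = rowSums(dZm))
  dB <- array(t(p$Wr) %*% dZm, dim(fw$B))
  # un-crop
  if (fw$crop > 0) {
    full_T <- dim(fw$B)[2] + 2 * fw$crop
    dBact <- array(0, c(dim(fw$B)[1], full_T, d[3]))
    dBact[, (fw$crop + 1):(full_T - fw$crop), ] <- dB
  } else dBact <- dB
  if (model$kind == "deep") {
    pb <- prelu_bwd(fw$preb, p$ab, dBact)
    g$ab <- pb$da
    g$bb <- rowSums(matrix(pb$dY, dim(pb$dY)[1]))
    cb <- conv_bwd(fw$inb, p$Wb, pb$dY, spec$bottleneck_kernel, 1L)
    g$Wb <- cb$dW
    dOut <- cb$dX
    for (l in rev(seq_len(spec$conv_layers))) {
      pl <- prelu_bwd(fw[[paste0("pre", l)]], p[[paste0("a", l)]], dOut)
      g[[paste0("a", l)]] <- pl$da
      g[[paste0("b", l)]] <- rowSums(matrix(pl$dY, dim(pl$dY)[1]))
      cl <- conv_bwd(fw[[paste0("in", l)]], p[[paste0("W", l)]], pl$dY,
                     spec$conv_kernel, 2L)
      g[[paste0("W", l)]] <- cl$dW
      dOut <- cl$dX
    }
    dA <- dOut
  } else {
    dPool <- avg_pool_bwd(dBact, spec$decimation)
    p1 <- prelu_bwd(fw$pre1, p$a1, dPool)
    g$a1 <- p1$da
    g$b1 <- rowSums(matrix(p1$dY, dim(p1$dY)[1]))
    c1 <- conv_bwd(fw$A, p$W1, p1$dY, model$ln_kernel, 1L)
    g$W1 <- c1$dW
    dA <- c1$dX
  }
  dS <- dA * symmetric_log_grad(fw$S)
  sk <- sinc_kernels(p$sinc_fc, p$sinc_bw, spec$sinc_len, spec$rate_hz,
                     grad = TRUE)
  cs <- conv_bwd(fw$X, sk$W, dS, spec$sinc_len, 1L)
  g$sinc_fc <- rowSums(cs$dW * sk$dW_dfc)
  g$sinc_bw <- rowSums(cs$dW * sk$dW_dbw)
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, only = NULL) {
  state$t <- state$t + 1
  upd <- if (is.null(only)) names(grads) else intersect(names(grads), only)
  for (nm in upd) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Slice a stimulus and aligned counts into training frames
#'
#' @param w a calibrated [waveform].
#' @param counts units x bins count matrix aligned to `w` at the encoder's
#'   output rate (bin width = decimation / rate).
#' @param cfg a [train_config()].
#' @param decimation encoder decimation factor (default 32).
#' @return list with `X` (1 x frame_in x n_frames cube) and `R`
#'   (units x out_len x n_frames cube).
#' @export
make_frames <- function(w, counts, cfg = train_config(), decimation = 32) {
  geom <- frame_geometry(cfg, w$rate_hz, decimation)
  bins_per_frame <- cfg$frame_in / decimation
  n_frames <- min(floor(length(w$samples) / cfg$frame_in),
                  floor(ncol(counts) / bins_per_frame))
  if (n_frames < 1) stop("stimulus shorter than one frame")
  X <- array(0, c(1, cfg$frame_in, n_frames))
  R <- array(0, c(nrow(counts), geom$out_len, n_frames))
  for (f in seq_len(n_frames)) {
    X[1, , f] <- w$samples[(f - 1) * cfg$frame_in + seq_len(cfg$frame_in)]
    cols <- (f - 1) * bins_per_frame + cfg$crop + seq_len(geom$out_len)
    R[, , f] <- counts[, cols]
  }
  list(X = X, R = R)
}

#' Train an encoder by Poisson regression with Adam
#'
#' Deterministic given `cfg$seed` (parameter initialization is the model's;
#' batch order is seeded here). The readout bias is warm-started at the log
#' mean count of each unit. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model an `encoder_model`.
#' @param X input cube (1 x frame_in x n_frames).
#' @param R target cube (units x out_len x n_frames).
#' @param cfg a [train_config()].
#' @param only optional character vector of parameter names to update
#'   (others frozen).
#' @param warm_start_bias set readout bias from mean counts (default TRUE).
#' @return the model, with `loss_history` (mean per-bin-per-unit Poisson
#'   loss per epoch, epoch 0 = before training) attached.
#' @export
train_encoder <- function(model, X, R, cfg = train_config(), only = NULL,
                          warm_start_bias = TRUE) {
  stopifnot(inherits(model, "encoder_model"))
  n <- dim(X)[3]
  if (warm_start_bias && (is.null(only) || "br" %in% only)) {
    mu <- pmax(rowMeans(matrix(R, dim(R)[1])), 1e-4)
    model$params$br <- log(mu)
  }
  state <- adam_init(model$params)
  history <- numeric(cfg$epochs + 1)
  history[1] <- encoder_eval_loss(model, X, R, cfg)
  order_seed <- substream_seed(cfg$seed, "batch_order")
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(order_seed + ep, sample.int(n))
    for (start in seq(1, n, by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1, n)]
      fw <- encoder_forward(model, X[, , idx, drop = FALSE], crop = cfg$crop,
                            cache = TRUE)
      loss <- poisson_loss(fw$Rhat, R[, , idx, drop = FALSE])
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (diverged); try a lower learning rate", ep))
      g <- encoder_backward(model, fw, R[, , idx, drop = FALSE])
      st <- adam_step(model$params, g, state, cfg$lr, only = only)
      model$params <- st$params; state <- st$state
    }
    history[ep + 1] <- encoder_eval_loss(model, X, R, cfg)
  }
  model$loss_history <- history
  model
}

#' Mean Poisson loss of a model on framed data
#'
#' @param model an `encoder_model`.
#' @param X,R input and target cubes as in [train_encoder()].
#' @param cfg a [train_config()] (for the crop).
#' @param batch evaluation batch size.
#' @return mean Poisson loss per unit-bin.
#' @export
encoder_eval_loss <- function(model, X, R, cfg = train_config(), batch = 16) {
  n <- dim(X)[3]; tot <- 0; cnt <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    fw <- encoder_forward(model, X[, , idx, drop = FALSE], crop = cfg$crop)
    tot <- tot + poisson_loss(fw$Rhat, R[, , idx, drop = FALSE])
    cnt <- cnt + length(fw$Rhat)
  }
  tot / cnt
}

#' Predict expected counts for framed input
#'
#' @param model an `encoder_model`.
#' @param X input cube (1 x frame_in x n_frames).
#' @param cfg a [train_config()] (for the crop).
#' @return units x out_len x n_frames cube of expected counts.
#' @export
predict_encoder <- function(model, X, cfg = train_config()) {
  n <- dim(X)[3]
  out <- NULL
  for (start in seq(1, n, by = 16)) {
    idx <- start:min(start + 15, n)
    fw <- encoder_forward(model, X[, , idx, drop = FALSE], crop = cfg$crop)
    out <- if (is.null(out)) fw$Rhat else
      array(c(out, fw$Rhat), c(dim(fw$Rhat)[1], dim(fw$Rhat)[2],
                               dim(out)[3] + dim(fw$Rhat)[3]))
  }
  out
}

#' Explainable variance explained by model predictions
#'
#' Per unit: 100 x cov(Rtest1, Rhat) / cov(Rtest1, Rtest2). 100% means the
#' prediction captures all trial-reproducible structure; units whose
#' across-repeat covariance is nonpositive are excluded (NA).
#'
#' @param Rhat predicted units x bins matrix.
#' @param Rtest1,Rtest2 recorded repeats over the same timeline.
#' @return numeric vector, percent per unit.
#' @export
explainable_variance_explained <- function(Rhat, Rtest1, Rtest2) {
  stopifnot(all(dim(Rhat) == dim(Rtest1)), all(dim(Rhat) == dim(Rtest2)))
  vapply(seq_len(nrow(Rhat)), function(u) {
    denom <- cov(Rtest1[u, ], Rtest2[u, ])
    if (denom <= 0) return(NA_real_)
    100 * cov(Rtest1[u, ], Rhat[u, ]) / denom
  }, numeric(1))
}

#' Extract bottleneck activations for a waveform
#'
#' Runs stages 1-3 on the (padded) waveform and returns the Db x T
#' activation matrix at the decimated rate (762.9395 Hz by default),
#' processing long inputs in overlapping chunks so results match framed
#' processing away from the extreme edges. Deterministic.
#'
#' @param model a trained `encoder_model` (kind "deep").
#' @param w a calibrated [waveform].
#' @return Db x T matrix with attributes `rate_hz` (output rate) and
#'   `padded` (TRUE when the input was extended to a whole number of bins).
#' @export
extract_bottleneck <- function(model, w) {
  stopifnot(inherits(model, "encoder_model"), inherits(w, "waveform"))
  dec <- model$spec$decimation
  x <- w$samples
  padded <- length(x) %% dec != 0 || length(x) < dec
  if (padded) x <- c(x, numeric(dec - (length(x) %% dec)))
  n_bins <- length(x) / dec
  margin_bins <- 64
  chunk_bins <- 512
  out <- matrix(0, model$spec$bottleneck, n_bins)
  b0 <- 0
  while (b0 < n_bins) {
    take <- min(chunk_bins, n_bins - b0)
    lo_b <- max(0, b0 - margin_bins)
    hi_b <- min(n_bins, b0 + take + margin_bins)
    seg <- x[(lo_b * dec + 1):(hi_b * dec)]
    Xc <- array(seg, c(1, length(seg), 1))
    fw <- encoder_forward(model, Xc, crop = 0, upto = "bottleneck")
    cols <- (b0 - lo_b) + seq_len(take)
    out[, b0 + seq_len(take)] <- fw$B[, cols, 1]
    b0 <- b0 + take
  }
  attr(out, "rate_hz") <- w$rate_hz / dec
  attr(out, "padded") <- padded
  out
}

#' Transfer a frozen encoder to a new animal
#'
#' Keeps every encoder parameter fixed and retrains only the per-unit linear
#' readout on the new animal's responses. Each new unit's readout weights
#' are initialized from a randomly chosen unit of the original model
#' (sampling with replacement when unit counts differ), or at random.
#'
#' @param model a trained `encoder_model`.
#' @param X,R framed stimulus and new-animal counts (as [make_frames()]).
#' @param cfg a [train_config()].
#' @param init `"mapped"` (default) or `"random"`.
#' @return the new model (encoder parameters bit-identical to the input
#'   model's) with `loss_history`.
#' @export
transfer_learn <- function(model, X, R, cfg = train_config(),
                           init = c("mapped", "random")) {
  init <- match.arg(init)
  new_M <- dim(R)[1]
  new_model <- model
  new_model$spec$n_units <- new_M
  with_seed(substream_seed(cfg$seed, "transfer_init"), {
    if (init == "mapped") {
      src <- sample.int(nrow(model$params$Wr), new_M, replace = TRUE)
      new_model$params$Wr <- model$params$Wr[src, , drop = FALSE]
      new_model$params$br <- model$params$br[src]
    } else {
      new_model$params$Wr <- matrix(rnorm(new_M * ncol(model$params$Wr),
                                          sd = 0.01), new_M)
      new_model$params$br <- rep(log(0.1), new_M)
    }
  })
  train_encoder(new_model, X, R, cfg, only = c("Wr", "br"),
                warm_start_bias = FALSE)
}

#' Save / load an encoder model as JSON + TSV weight files
#'
#' @param model an `encoder_model`.
#' @param dir checkpoint directory.
#' @return `dir` (save) or the model (load).
#' @export
save_encoder <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(spec = unclass(model$spec), kind = model$kind,
               ln_kernel = model$ln_kernel,
               param_names = names(model$params),
               param_dims = lapply(model$params, function(x)
                 if (is.matrix(x)) dim(x) else length(x)))
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(model$params)) {
    utils::write.table(model$params[[nm]],
                       file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  spec <- do.call(encoder_spec, meta$spec[setdiff(names(meta$spec),
                                                  "decimation")])
  params <- list()
  for (nm in meta$param_names) {
    v <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                     sep = "\t"))
    dimnames(v) <- NULL
    d <- meta$param_dims[[nm]]
    params[[nm]] <- if (length(d) == 2) v else as.numeric(v)
  }
  structure(list(spec = spec, params = params, kind = meta$kind,
                 ln_kernel = meta$ln_kernel),
            class = "encoder_model")
}
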