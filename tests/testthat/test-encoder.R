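test_that("symmetric log is odd, monotone, with the stated fixed points", {
  expect_equal(symmetric_log(0), 0)
  expect_equal(symmetric_log(exp(1) - 1), 1)
  expect_equal(symmetric_log(-(exp(1) - 1)), -1)
  x <- seq(-5, 5, 0.1)
  expect_equal(symmetric_log(-x), -symmetric_log(x))
  expect_true(all(diff(symmetric_log(x)) > 0))
})

test_that("Poisson loss matches its elementwise definition and is stationary at truth", {
  set.seed(1)
  Rhat <- matrix(runif(12, 0.1, 2), 3)
  R <- matrix(rpois(12, 1), 3)
  expect_equal(poisson_loss(Rhat, R), sum(Rhat - R * log(Rhat)),
               tolerance = 1e-12)
  # R = 0 everywhere: loss reduces to sum(Rhat)
  expect_equal(poisson_loss(Rhat, R * 0), sum(Rhat), tolerance = 1e-12)
  # stationarity at Rhat = R (positive counts): any perturbation increases it
  Rpos <- matrix(c(1, 2, 3, 4), 2)
  base <- poisson_loss(Rpos, Rpos)
  for (i in 1:4) for (d in c(-0.01, 0.01)) {
    Rp <- Rpos; Rp[i] <- Rp[i] + d
    expect_gt(poisson_loss(Rp, Rpos), base)
  }
  expect_error(poisson_loss(matrix(-1, 1, 1), matrix(1, 1, 1)), "positive")
})

test_that("frame geometry: 32x decimation plus 32-bin crops", {
  g <- frame_geometry(train_config(frame_in = 8192))
  expect_identical(g$out_len, 192)
  expect_equal(g$out_rate_hz, 762.9395, tolerance = 1e-4)
  expect_equal(g$out_rate_hz, 24414.0625 / 32, tolerance = 1e-10)
  g2 <- frame_geometry(train_config(frame_in = 4096))
  expect_identical(g2$out_len, 64)
  expect_error(frame_geometry(train_config(frame_in = 1000)), "divisible")
})

test_that("the network obeys the shape contract for any whole number of frames", {
  spec <- tiny_spec()
  m <- encoder_init(spec, seed = 1)
  for (nf in c(1, 3)) {
    X <- array(rnorm(8192 * nf, sd = 0.1), c(1, 8192, nf))
    fw <- icdyn:::encoder_forward(m, X, crop = 32)
    expect_equal(dim(fw$Rhat), c(4, 192, nf))
    expect_true(all(fw$Rhat > 0))
  }
})

test_that("training is seed deterministic and fits a constant-rate target", {
  spec <- tiny_spec()
  set.seed(2)
  X <- array(rnorm(8192 * 8, sd = 0.05), c(1, 8192, 8))
  R <- array(rpois(4 * 192 * 8, 0.3), c(4, 192, 8))
  cfg <- train_config(frame_in = 8192, batch = 4, epochs = 2, lr = 1e-3,
                      seed = 7)
  m1 <- train_encoder(encoder_init(spec, seed = 3), X, R, cfg)
  m2 <- train_encoder(encoder_init(spec, seed = 3), X, R, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params$Wr, m2$params$Wr)
  # constant-rate target: mean prediction converges to the mean count
  pr <- predict_encoder(m1, X, cfg)
  for (u in 1:4)
    expect_lt(abs(mean(pr[u, , ]) - mean(R[u, , ])) / mean(R[u, , ]), 0.05)
  # training loss decreased
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
})

test_that("explainable variance explained is 100% against the second repeat", {
  tp <- fixture("toy_repeats", toy_repeats())
  eve <- explainable_variance_explained(tp$r2, tp$r1, tp$r2)
  expect_equal(eve, rep(100, nrow(tp$r1)), tolerance = 1e-9)
  # uncorrelated prediction: ~ 0%
  set.seed(3)
  junk <- matrix(rpois(length(tp$r1), 2), nrow(tp$r1))
  eve0 <- explainable_variance_explained(junk, tp$r1, tp$r2)
  expect_lt(max(abs(eve0)), 15)
  # the true rate function explains ~ all explainable variance
  evet <- explainable_variance_explained(tp$rates, tp$r1, tp$r2)
  expect_equal(mean(evet), 100, tolerance = 5)
})

test_that("the LN baseline shares the output contract with fewer parameters", {
  spec <- tiny_spec()
  deep <- encoder_init(spec, seed = 1)
  ln <- build_ln_baseline(spec, ln_kernel = 64, seed = 1)
  X <- array(rnorm(8192, sd = 0.1), c(1, 8192, 1))
  fd <- icdyn:::encoder_forward(deep, X, crop = 32)
  fl <- icdyn:::encoder_forward(ln, X, crop = 32)
  expect_equal(dim(fd$Rhat), dim(fl$Rhat))
  # at the full-scale architecture the LN model is the smaller one
  spec_full <- encoder_spec(n_units = 50)
  expect_lt(n_params(build_ln_baseline(spec_full)),
            n_params(encoder_init(spec_full)))
})

test_that("transfer learning freezes the encoder bitwise and reuses readouts", {
  spec <- tiny_spec()
  set.seed(4)
  X <- array(rnorm(8192 * 6, sd = 0.05), c(1, 8192, 6))
  R <- array(rpois(4 * 192 * 6, 0.3), c(4, 192, 6))
  cfg <- train_config(frame_in = 8192, batch = 3, epochs = 1, lr = 1e-3,
                      seed = 5)
  m <- train_encoder(encoder_init(spec, seed = 6), X, R, cfg)
  # new animal with a different unit count
  R_new <- array(rpois(7 * 192 * 6, 0.3), c(7, 192, 6))
  tm <- transfer_learn(m, X, R_new, cfg)
  enc_names <- setdiff(names(m$params), c("Wr", "br"))
  for (nm in enc_names) expect_identical(tm$params[[nm]], m$params[[nm]])
  expect_equal(nrow(tm$params$Wr), 7)
  expect_lt(tail(tm$loss_history, 1), tm$loss_history[1])
  # a permuted copy of the original units reaches the original fit quality:
  # mapped initialization starts from existing readouts
  perm <- c(3, 1, 4, 2)
  tm2 <- transfer_learn(m, X, R[perm, , , drop = FALSE],
                        train_config(frame_in = 8192, batch = 3, epochs = 0,
                                     lr = 1e-3, seed = 5))
  expect_true(all(tm2$params$Wr %in% m$params$Wr))
})

test_that("bottleneck extraction is deterministic and shift equivariant", {
  spec <- tiny_spec()
  m <- encoder_init(spec, seed = 8)
  set.seed(9)
  w <- waveform(rnorm(24414 * 2, sd = 0.05))
  B1 <- extract_bottleneck(m, w)
  expect_equal(nrow(B1), 3)
  expect_equal(attr(B1, "rate_hz"), w$rate_hz / 32, tolerance = 1e-9)
  expect_identical(B1, extract_bottleneck(m, w))
  # silence: near-constant activations
  Bs <- extract_bottleneck(m, waveform(numeric(8192)))
  expect_lt(max(apply(Bs, 1, sd)), 1e-8)
  # shifting the input by 32 samples shifts activations by one bin (interior)
  w2 <- waveform(c(numeric(32), w$samples))
  B2 <- extract_bottleneck(m, w2)
  interior <- 100:1300
  expect_equal(B2[, interior + 1], B1[, interior], tolerance = 1e-6)
})
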