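test_that("RDMs match hand-computed correlations on a toy instance", {
  # 3 sounds, 2 channels, 4 bins each: build the trajectory matrix by hand
  traj <- rbind(s1 = c(1, 2, 3, 4, 0, 1, 0, 1),
                s2 = c(1, 2, 3, 4, 0, 1, 0, 1) * 2 + 5,  # perfectly correlated
                s3 = c(4, 3, 2, 1, 1, 0, 1, 0))          # anti-correlated
  rdm <- compute_rdm(traj)
  expect_equal(diag(rdm), rep(0, 3), ignore_attr = TRUE)
  expect_equal(rdm[1, 2], 0, tolerance = 1e-12)
  expect_equal(rdm[1, 3], 1 - cor(traj[1, ], traj[3, ]), tolerance = 1e-12)
  expect_equal(rdm, t(rdm), ignore_attr = TRUE)
  expect_true(all(rdm >= 0 & rdm <= 2))
  # global scaling of all trajectories leaves the RDM unchanged
  expect_equal(unclass(compute_rdm(traj * 3.7)), unclass(rdm),
               tolerance = 1e-12)
  expect_warning(compute_rdm(rbind(traj, s4 = rep(1, 8))), "zero-variance")
})

test_that("trajectory extraction tiles sounds and averages instances", {
  set.seed(1)
  X <- matrix(rnorm(2 * 100), 2)
  attr(X, "rate_hz") <- 100
  labels <- rbind(
    icdyn:::label_row("consonant", 0.0, 0.2, consonant_id = 1, talker_id = 1),
    icdyn:::label_row("silence", 0.2, 0.1),
    icdyn:::label_row("consonant", 0.3, 0.2, consonant_id = 1, talker_id = 2),
    icdyn:::label_row("silence", 0.5, 0.1),
    icdyn:::label_row("consonant", 0.6, 0.2, consonant_id = 2, talker_id = 1))
  tr <- sound_trajectories(X, labels)
  expect_equal(nrow(tr), 2)          # instances of consonant 1 averaged
  seg1 <- as.vector(t(X[, 1:20])); seg2 <- as.vector(t(X[, 31:50]))
  expect_equal(tr[1, ], (seg1 + seg2) / 2, ignore_attr = TRUE)
  # keeping talker identity separates the instances
  tr3 <- sound_trajectories(X, labels,
                            group_cols = c("kind", "consonant_id", "talker_id"))
  expect_equal(nrow(tr3), 3)
})

test_that("RDM similarity is symmetric, 1 on self, and null under permutation", {
  set.seed(2)
  traj <- matrix(rnorm(12 * 40), 12)
  rdm <- compute_rdm(traj)
  expect_equal(rdm_similarity(rdm, rdm), 1)
  traj2 <- traj + matrix(rnorm(12 * 40, sd = 0.5), 12)
  rdm2 <- compute_rdm(traj2)
  expect_equal(rdm_similarity(rdm, rdm2), rdm_similarity(rdm2, rdm))
  # permutation null: shuffling sound identities kills the correlation
  nulls <- vapply(1:200, function(i) {
    p <- sample(12)
    rdm_similarity(rdm, compute_rdm(traj2[p, ]))
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.1)
  expect_gt(rdm_similarity(rdm, rdm2), quantile(nulls, 0.99))
  const_rdm <- matrix(0.5, 3, 3); diag(const_rdm) <- 0
  expect_warning(rdm_similarity(const_rdm, rdm[1:3, 1:3]), "constant")
})

test_that("best intensity maximizes RDM similarity with low-level tie breaking", {
  set.seed(3)
  traj <- matrix(rnorm(8 * 30), 8)
  ref <- compute_rdm(traj)
  cands <- list(
    `55` = compute_rdm(traj + matrix(rnorm(240, sd = 2), 8)),
    `70` = compute_rdm(traj),
    `85` = compute_rdm(traj + matrix(rnorm(240, sd = 1), 8)))
  out <- best_intensity(ref, cands)
  expect_equal(out$level, 70)
  expect_equal(out$similarity, 1)
  # exact tie: the lower level wins
  cands2 <- list(`70` = compute_rdm(traj), `85` = compute_rdm(traj))
  expect_equal(best_intensity(ref, cands2)$level, 70)
  expect_error(best_intensity(ref, list()), "candidate")
})

test_that("canonical correlations match stats::cancor and invariance laws", {
  set.seed(4)
  X <- matrix(rnorm(3 * 400), 3)
  M <- matrix(rnorm(9), 3); diag(M) <- diag(M) + 2
  Y <- M %*% X
  al <- cca_align(X, Y)
  expect_equal(al$rho, rep(1, 3), tolerance = 1e-8)
  # independent dynamics: correlations near the permutation null
  Z <- matrix(rnorm(3 * 400), 3)
  al0 <- cca_align(X, Z)
  expect_lt(max(al0$rho), 0.35)
  # oracle: base-R cancor on the same data
  Y2 <- X + matrix(rnorm(3 * 400, sd = 1), 3)
  al2 <- cca_align(X, Y2)
  cc <- stats::cancor(t(X), t(Y2))
  expect_equal(al2$rho, cc$cor, tolerance = 1e-8)
  # canonical variates are uncorrelated with unit variance
  expect_equal(cov(al2$U), diag(3), tolerance = 1e-8)
  # invariance to invertible transforms of either argument
  al3 <- cca_align(matrix(rnorm(9), 3) %*% X + 0.0, Y2)
  expect_equal(al3$rho, al2$rho, tolerance = 1e-6)
  # rank-deficient input: reduced components, flagged
  Xr <- rbind(X[1, ], X[1, ], X[2, ])
  alr <- cca_align(Xr, Y2)
  expect_true(alr$flagged)
  expect_lt(alr$rank, 3)
})

test_that("weighted CCA similarity is 1 on self, bounded, symmetric, noise monotone", {
  set.seed(5)
  X <- matrix(rnorm(4 * 600), 4) * seq(2, 0.8, length.out = 4)
  expect_equal(cca_similarity(X, X), 1, tolerance = 1e-8)
  sims <- vapply(c(0.2, 0.6, 1.2, 2.5), function(sg) {
    Y <- X + matrix(rnorm(4 * 600, sd = sg), 4)
    cca_similarity(X, Y)
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
  expect_true(all(sims <= 1 + 1e-12))
  Y <- X + matrix(rnorm(4 * 600, sd = 0.7), 4)
  expect_equal(cca_similarity(X, Y), cca_similarity(Y, X), tolerance = 1e-10)
  # term-by-term against a hand-computed 2-dim instance
  X2 <- matrix(rnorm(2 * 500), 2)
  Y2 <- X2 + matrix(rnorm(2 * 500, sd = 0.5), 2)
  al <- cca_align(X2, Y2)
  Xt <- scale(t(X2), scale = FALSE); Yt <- scale(t(Y2), scale = FALSE)
  manual <- 0
  for (d in 1:2) {
    u <- al$U[, d]; v <- al$V[, d]
    rho_d <- cor(u, v)
    Xh <- u %*% (crossprod(u, Xt) / sum(u^2))
    Yh <- v %*% (crossprod(v, Yt) / sum(v^2))
    wx <- cor(as.vector(Xh), as.vector(Xt))^2
    wy <- cor(as.vector(Yh), as.vector(Yt))^2
    manual <- manual + rho_d * (wx + wy) / 2
  }
  expect_equal(cca_similarity(X2, Y2), manual, tolerance = 1e-12)
})

test_that("multiway CCA recovers a latent shared by all datasets", {
  set.seed(6)
  T_ <- 800
  shared <- rnorm(T_)
  dats <- lapply(1:3, function(i)
    rbind(shared + rnorm(T_, sd = 0.4),
          rnorm(T_), rnorm(T_)))
  mc <- mcca_align(dats)
  # leading joint component tracks the shared latent
  expect_gt(abs(cor(mc$scores[, 1], shared)), 0.9)
  # identical datasets: first-component scores correlate perfectly pairwise
  same <- lapply(1:3, function(i) dats[[1]])
  mcs <- mcca_align(same)
  for (i in 2:3)
    expect_equal(abs(cor(mcs$per_dataset_scores[[1]][, 1],
                         mcs$per_dataset_scores[[i]][, 1])), 1,
                 tolerance = 1e-9)
  # permuting time in one dataset collapses the shared component
  datp <- dats; datp[[3]] <- datp[[3]][, sample(T_)]
  mcp <- mcca_align(datp)
  c_full <- mean(vapply(1:2, function(i)
    abs(cor(mc$per_dataset_scores[[i]][, 1], mc$per_dataset_scores[[3]][, 1])),
    numeric(1)))
  c_perm <- mean(vapply(1:2, function(i)
    abs(cor(mcp$per_dataset_scores[[i]][, 1], mcp$per_dataset_scores[[3]][, 1])),
    numeric(1)))
  expect_lt(c_perm, c_full / 2)
})

test_that("envelope-tracking CV matches the sinusoid closed form", {
  expect_equal(envelope_tracking_cv(matrix(2, 3, 100)), 0)
  t <- seq(0, 1, length.out = 2000)
  for (depth in c(0.3, 0.8)) {
    X <- rbind(2 * (1 + depth * sin(2 * pi * 10 * t)),
               5 * (1 + depth * sin(2 * pi * 10 * t)))
    expect_equal(envelope_tracking_cv(X), depth / sqrt(2), tolerance = 0.01)
  }
  # nonpositive-mean channels are excluded
  X2 <- rbind(1 + 0.5 * sin(2 * pi * 5 * t), -1 + 0 * t)
  expect_equal(envelope_tracking_cv(X2), 0.5 / sqrt(2), tolerance = 0.01)
})

test_that("FRAs locate a channel's preferred frequency on the tone grid", {
  ts <- fixture("tone_stream", make_tone_stream(seed = 1))
  rate <- 762.9395
  n_bins <- ceiling(tail(ts$labels$onset_s + ts$labels$duration_s, 1) * rate)
  freqs <- tone_freq_grid()
  # synthetic channel tuned to 2 kHz, level-monotone
  X <- matrix(0, 2, n_bins)
  segs <- ts$labels[ts$labels$kind == "tone", ]
  for (i in seq_len(nrow(segs))) {
    b0 <- floor(segs$onset_s[i] * rate) + 1
    b1 <- b0 + floor(segs$duration_s[i] * rate) - 1
    gain <- exp(-(log2(segs$frequency_hz[i] / 2000))^2) *
      (segs$intensity_db_spl[i] / 100)
    X[1, b0:b1] <- gain
    X[2, b0:b1] <- 0.5
  }
  fra <- compute_fra(X, ts$labels, rate_hz = rate)
  expect_equal(dim(fra$fra), c(2, 21, 16))
  low <- fra$fra[1, , 4]      # a fixed moderate level
  expect_equal(freqs[which.max(low)], 2000, tolerance = 0.15)
  expect_true(all(fra$fra_norm >= 0 & fra$fra_norm <= 1, na.rm = TRUE))
})

test_that("consonant decoding is near-perfect when classes separate and errors early", {
  set.seed(7)
  n_cls <- 6; n_inst <- 12
  proto <- matrix(rnorm(n_cls * 20, sd = 3), n_cls)
  feats <- proto[rep(1:n_cls, each = n_inst), ] +
    matrix(rnorm(n_cls * n_inst * 20, sd = 0.2), n_cls * n_inst)
  cls <- factor(rep(1:n_cls, each = n_inst))
  out <- decode_consonants(feats, cls, folds = 10, seed = 1)
  expect_gt(out$accuracy, 0.99)
  small <- c(1:5, 13:17)     # two classes with 5 instances each
  expect_error(decode_consonants(feats[small, ], cls[small], folds = 10),
               "folds")
  # two-class toy agrees with a direct SVM fit on the same folds
  f2 <- feats[cls %in% c("1", "2"), ]; c2 <- droplevels(cls[cls %in% c("1", "2")])
  out2 <- decode_consonants(f2, c2, folds = 4, seed = 2)
  fold_id <- integer(nrow(f2))
  set.seed(icdyn:::substream_seed(2, "folds"))
  for (cl in levels(c2)) {
    idx <- sample(which(c2 == cl))
    fold_id[idx] <- rep_len(1:4, length(idx))
  }
  pred <- factor(rep(NA, nrow(f2)), levels = levels(c2))
  for (f in 1:4) {
    fit <- e1071::svm(f2[fold_id != f, ], c2[fold_id != f], kernel = "linear",
                      cost = 1, scale = FALSE)
    pred[fold_id == f] <- predict(fit, f2[fold_id == f, ])
  }
  expect_equal(out2$accuracy, mean(pred == c2), tolerance = 1e-12)
})

test_that("masking decorrelates dynamics most at matched center frequencies", {
  # linear filterbank stand-in for an encoder: third-octave band envelopes
  fb <- function(w) {
    cfs <- c(1000, 2000, 4000)
    t(vapply(cfs, function(cf)
      icdyn:::binned_band_envelope(w, cf, 0.5, 32 / w$rate_hz),
      numeric(floor(length(w$samples) / 32))))
  }
  grid <- masking_correlation_grid(fb, target_cfs = 2000,
                                   masker_cfs = c(500, 2000, 8000),
                                   levels = 70, seed = 1)
  expect_equal(nrow(grid), 3)
  on_cf <- grid$correlation[grid$masker_cf == 2000]
  off_cf <- grid$correlation[grid$masker_cf != 2000]
  expect_lt(on_cf, min(off_cf))
  expect_true(all(grid$correlation < 1))
})
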