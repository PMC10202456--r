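#' Per-sound trajectory matrix from latent dynamics
#'
#' Cuts a Db x T dynamics matrix into per-sound segments using the stimulus
#' labels, truncates all segments to the shortest segment length, flattens
#' each to one row (all channels' time courses concatenated), and averages
#' rows that share a sound identity. With the default grouping, instances of
#' the same consonant (different talkers) are averaged; pass `"talker_id"`
#' in `group_cols` to keep instances separate.
#'
#' @param X Db x T dynamics matrix (PCA projections or bottleneck
#'   activations).
#' @param labels stimulus label data frame.
#' @param rate_hz bin rate of `X` (default: its `rate_hz` attribute).
#' @param group_cols label columns defining sound identity.
#' @return S x (Db * TS) matrix with sound ids as row names.
#' @export
sound_trajectories <- function(X, labels, rate_hz = attr(X, "rate_hz"),
                               group_cols = c("kind", "frequency_hz",
                                              "intensity_db_spl",
                                              "mod_freq_hz", "mod_depth",
                                              "consonant_id")) {
  stopifnot(!is.null(rate_hz))
  segs <- labels[labels$kind != "silence", , drop = FALSE]
  first <- floor(segs$onset_s * rate_hz) + 1
  len <- floor(segs$duration_s * rate_hz)
  ts <- min(len)
  rows <- t(vapply(seq_len(nrow(segs)), function(i) {
    as.vector(t(X[, first[i] + seq_len(ts) - 1, drop = FALSE]))
  }, numeric(ts * nrow(X))))
  ids <- apply(segs[, intersect(group_cols, names(segs)), drop = FALSE], 1,
               function(r) paste(r[!is.na(r)], collapse = "|"))
  sizes <- table(ids)
  agg <- rowsum(rows, ids)
  agg / as.vector(sizes[rownames(agg)])
}

#' Representational dissimilarity matrix (RDM)
#'
#' S x S matrix with entries 1 - Pearson correlation between pairs of
#' flattened per-sound trajectories.
#'
#' @param traj S x (Db*TS) trajectory matrix ([sound_trajectories()]).
#' @return an `rdm` object (matrix with sound labels); zero-variance sounds
#'   give NA entries with a warning.
#' @export
compute_rdm <- function(traj) {
  sds <- apply(traj, 1, sd)
  if (any(sds == 0)) warning("zero-variance trajectories: NA entries in RDM")
  r <- suppressWarnings(cor(t(traj)))
  r[!is.finite(r)] <- NA
  d <- 1 - r
  diag(d) <- 0
  structure(d, class = c("rdm", "matrix"))
}

#' Correlation between two RDMs
#'
#' Pearson correlation of the vectorized upper triangles (diagonal
#' excluded). Symmetric in its arguments.
#'
#' @param rdm1,rdm2 RDMs over the same sounds in the same order.
#' @return scalar correlation (NA with a warning for constant RDMs).
#' @export
rdm_similarity <- function(rdm1, rdm2) {
  stopifnot(all(dim(rdm1) == dim(rdm2)))
  v1 <- rdm1[upper.tri(rdm1)]
  v2 <- rdm2[upper.tri(rdm2)]
  if (length(v1) < 2) {
    warning("need at least 3 sounds for an RDM correlation")
    return(NA_real_)
  }
  if (isTRUE(sd(v1, na.rm = TRUE) == 0) || isTRUE(sd(v2, na.rm = TRUE) == 0) ||
      !is.finite(sd(v1, na.rm = TRUE)) || !is.finite(sd(v2, na.rm = TRUE))) {
    warning("constant RDM: similarity undefined")
    return(NA_real_)
  }
  cor(v1, v2, use = "complete.obs")
}

#' Best presentation intensity relative to a reference RDM
#'
#' The intensity whose RDM has the highest point-by-point correlation with
#' the reference RDM; ties break toward the lower intensity.
#'
#' @param reference an RDM at a fixed level.
#' @param candidates named list of RDMs, names = intensities (dB SPL).
#' @return list with `level` and `similarity`.
#' @export
best_intensity <- function(reference, candidates) {
  if (length(candidates) == 0) stop("no candidate RDMs supplied")
  levels <- as.numeric(names(candidates))
  sims <- vapply(candidates, function(r) rdm_similarity(reference, r),
                 numeric(1))
  ord <- order(levels)
  levels <- levels[ord]; sims <- unname(sims[ord])
  i <- which.max(sims)     # first (lowest level) among ties
  list(level = levels[i], similarity = sims[i],
       similarities = setNames(sims, levels))
}

qr_basis <- function(Xt) {
  qx <- qr(Xt)
  r <- qx$rank
  list(Q = qr.Q(qx)[, seq_len(r), drop = FALSE],
       R = qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE],
       pivot = qx$pivot[seq_len(r)], rank = r)
}

#' Canonical correlation alignment of two sets of latent dynamics
#'
#' Computes canonical components via QR factorization and singular value
#' decomposition of the centered dynamics: U = X A and V = Y B maximize the
#' per-component correlations, which are returned in descending order. The
#' alignment is invariant to invertible linear transforms of either input.
#' Rank-deficient dynamics yield a reduced number of components with
#' `flagged = TRUE`.
#'
#' @param X,Y D x T latent-dynamics matrices (equal T, T >> D).
#' @return a `cca_alignment` with `A`, `B` (coefficient matrices), `rho`
#'   (canonical correlations), `U`, `V` (T x k aligned dynamics), `rank`.
#' @export
cca_align <- function(X, Y) {
  stopifnot(ncol(X) == ncol(Y))
  T_ <- ncol(X)
  Xt <- scale(t(X), scale = FALSE)
  Yt <- scale(t(Y), scale = FALSE)
  bx <- qr_basis(Xt); by <- qr_basis(Yt)
  k <- min(bx$rank, by$rank)
  s <- svd(crossprod(bx$Q, by$Q), nu = k, nv = k)
  A <- matrix(0, nrow(X), k)
  B <- matrix(0, nrow(Y), k)
  A[bx$pivot, ] <- backsolve(bx$R, s$u[, seq_len(k), drop = FALSE]) *
    sqrt(T_ - 1)
  B[by$pivot, ] <- backsolve(by$R, s$v[, seq_len(k), drop = FALSE]) *
    sqrt(T_ - 1)
  structure(list(A = A, B = B, rho = pmin(pmax(s$d[seq_len(k)], 0), 1),
                 U = Xt %*% A, V = Yt %*% B, rank = k,
                 flagged = k < min(nrow(X), nrow(Y))),
            class = "cca_alignment")
}

rank1_recon_cor <- function(u, Mt) {
  # correlation between M and its regression reconstruction from the single
  # time course u (both centered, T x D)
  beta <- crossprod(u, Mt) / sum(u^2)
  Mhat <- u %*% beta
  cor(as.vector(Mhat), as.vector(Mt))
}

#' Weighted CCA similarity of two sets of latent dynamics
#'
#' Sum over components of the canonical correlation weighted by the average
#' squared correlation between each component's rank-1 reconstruction of the
#' dynamics and the dynamics themselves:
#' `sum_d rho(U_d, V_d) * (rho(Xhat_d, X)^2 + rho(Yhat_d, Y)^2) / 2`.
#' Reconstructions regress the dynamics on the component time course, so for
#' full-rank X the weights sum to 1 and `cca_similarity(X, X)` is exactly 1.
#' Bounded above by 1 and symmetric in its arguments.
#'
#' @param X,Y D x T latent-dynamics matrices.
#' @param align optional precomputed [cca_align()] result for (X, Y).
#' @return scalar similarity.
#' @export
cca_similarity <- function(X, Y, align = NULL) {
  if (is.null(align)) align <- cca_align(X, Y)
  Xt <- scale(t(X), scale = FALSE)
  Yt <- scale(t(Y), scale = FALSE)
  sim <- 0
  for (d in seq_len(align$rank)) {
    rho_d <- cor(align$U[, d], align$V[, d])
    wx <- rank1_recon_cor(align$U[, d, drop = FALSE], Xt)^2
    wy <- rank1_recon_cor(align$V[, d, drop = FALSE], Yt)^2
    sim <- sim + rho_d * (wx + wy) / 2
  }
  sim
}

#' Multiway CCA of three or more sets of latent dynamics
#'
#' Each dataset is whitened by PCA (keeping components above a relative
#' eigenvalue floor of 1e-8), the whitened datasets are concatenated along
#' channels, and PCA of the concatenation yields joint components ordered by
#' shared variance. Per-dataset maps project each original dataset onto the
#' joint components.
#'
#' @param dynamics list of D_i x T matrices (equal T).
#' @return list with `scores` (T x k joint components), `maps` (per-dataset
#'   D_i x k), `per_dataset_scores`, `eig` (joint eigenvalues; values near
#'   the number of datasets indicate components shared by all), `flagged`
#'   (any rank deficiency).
#' @export
mcca_align <- function(dynamics) {
  stopifnot(length(dynamics) >= 2)
  T_ <- unique(vapply(dynamics, ncol, numeric(1)))
  if (length(T_) != 1) stop("all datasets must share the time axis")
  whitened <- list(); maps_w <- list(); flagged <- FALSE
  for (i in seq_along(dynamics)) {
    Xt <- scale(t(dynamics[[i]]), scale = FALSE)
    e <- eigen(cov(Xt), symmetric = TRUE)
    keep <- e$values > 1e-8 * e$values[1]
    if (!all(keep)) flagged <- TRUE
    W <- e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
    whitened[[i]] <- Xt %*% W
    maps_w[[i]] <- W
  }
  Ycat <- do.call(cbind, whitened)
  sv <- svd(Ycat)
  k <- sum(sv$d > 1e-8 * sv$d[1])
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = nrow(sv$u))
  eig <- sv$d[seq_len(k)]^2 / (nrow(Ycat) - 1)
  offset <- 0
  maps <- list(); per_scores <- list()
  for (i in seq_along(dynamics)) {
    ki <- ncol(whitened[[i]])
    vi <- sv$v[offset + seq_len(ki), seq_len(k), drop = FALSE]
    maps[[i]] <- maps_w[[i]] %*% vi
    per_scores[[i]] <- whitened[[i]] %*% vi
    offset <- offset + ki
  }
  list(scores = scores, maps = maps, per_dataset_scores = per_scores,
       eig = eig, flagged = flagged)
}

#' Envelope-tracking strength as a coefficient of variation
#'
#' SD/mean of each channel's condition-mean activation time course over a
#' steady-state segment, averaged across channels with positive mean
#' (channels with nonpositive mean are excluded).
#'
#' @param X Db x T condition-mean activations (ramps excluded).
#' @return scalar CV (0 for constant activations).
#' @export
envelope_tracking_cv <- function(X) {
  mu <- rowMeans(X)
  keep <- mu > 0
  if (!any(keep)) return(NA_real_)
  mean(apply(X[keep, , drop = FALSE], 1, sd) / mu[keep])
}

#' Frequency response areas (FRAs) from tone-stream dynamics
#'
#' Mean activation per (frequency, intensity) cell for each channel.
#'
#' @param X Db x T dynamics over a tone stream.
#' @param labels the tone stream's label table.
#' @param rate_hz bin rate of `X`.
#' @return list with `fra` (channels x freqs x levels, NA for missing
#'   cells), `fra_norm` (per-channel min-max normalized), `freqs`, `levels`.
#' @export
compute_fra <- function(X, labels, rate_hz = attr(X, "rate_hz")) {
  segs <- labels[labels$kind == "tone", , drop = FALSE]
  freqs <- sort(unique(segs$frequency_hz))
  levels <- sort(unique(segs$intensity_db_spl))
  fra <- array(NA_real_, c(nrow(X), length(freqs), length(levels)))
  first <- floor(segs$onset_s * rate_hz) + 1
  len <- floor(segs$duration_s * rate_hz)
  for (i in seq_len(nrow(segs))) {
    fi <- match(segs$frequency_hz[i], freqs)
    li <- match(segs$intensity_db_spl[i], levels)
    m <- rowMeans(X[, first[i] + seq_len(len[i]) - 1, drop = FALSE])
    fra[, fi, li] <- if (all(is.na(fra[, fi, li]))) m else
      (fra[, fi, li] + m) / 2
  }
  rng <- apply(fra, 1, range, na.rm = TRUE)
  fra_norm <- sweep(sweep(fra, 1, rng[1, ], "-"), 1,
                    pmax(rng[2, ] - rng[1, ], 1e-12), "/")
  list(fra = fra, fra_norm = fra_norm, freqs = freqs, levels = levels)
}

#' Decode consonant identity from latent dynamics
#'
#' One-vs-one linear support-vector classifiers over all class pairs with
#' max-wins voting and stratified tenfold cross-validation.
#'
#' @param features n_instances x p matrix (flattened per-instance dynamics).
#' @param classes factor of consonant labels (each class needs at least
#'   `folds` instances).
#' @param folds number of cross-validation folds (default 10).
#' @param cost SVM regularization constant (default 1).
#' @param seed integer seed for fold assignment.
#' @return list with `accuracy`, `fold_accuracy`, `predicted`.
#' @export
decode_consonants <- function(features, classes, folds = 10, cost = 1,
                              seed = 1) {
  classes <- factor(classes)
  if (any(table(classes) < folds))
    stop("every class needs at least `folds` instances")
  n <- nrow(features)
  fold_id <- integer(n)
  with_seed(substream_seed(seed, "folds"), {
    for (cl in levels(classes)) {
      idx <- sample(which(classes == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  pred <- factor(rep(NA, n), levels = levels(classes))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- e1071::svm(features[tr, , drop = FALSE], classes[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred[!tr] <- predict(fit, features[!tr, , drop = FALSE])
  }
  fold_acc <- vapply(seq_len(folds), function(f)
    mean(pred[fold_id == f] == classes[fold_id == f]), numeric(1))
  list(accuracy = mean(pred == classes), fold_accuracy = fold_acc,
       predicted = pred)
}

#' Masking-induced decorrelation of latent dynamics
#'
#' For every (target CF, masker CF, level) condition, presents the
#' narrowband target alone and summed with the masker, extracts latent
#' dynamics for both, and reports their point-by-point correlation. The
#' target waveform is identical in both presentations.
#'
#' @param model an `encoder_model`, or any function mapping a [waveform] to
#'   a dynamics matrix.
#' @param target_cfs,masker_cfs center-frequency grids in Hz.
#' @param levels presentation levels in dB SPL.
#' @param seed integer seed (noise carriers).
#' @param rate_hz sampling rate.
#' @return long-format data frame (target_cf, masker_cf, level,
#'   correlation).
#' @export
masking_correlation_grid <- function(model, target_cfs = narrowband_cf_grid(),
                                     masker_cfs = narrowband_cf_grid(),
                                     levels = 70, seed = 1,
                                     rate_hz = 24414.0625) {
  act <- if (is.function(model)) model else
    function(w) extract_bottleneck(model, w)
  out <- list()
  for (lv in levels) for (tcf in target_cfs) {
    alone <- NULL
    for (mcf in masker_cfs) {
      pair <- make_narrowband_pair(tcf, mcf, level = lv, rate_hz = rate_hz,
                                   seed = seed)
      if (is.null(alone)) alone <- act(pair$target)
      mixed <- waveform(pair$target$samples + pair$masker$samples, rate_hz)
      both <- act(mixed)
      if (!all(dim(both) == dim(alone))) stop("misaligned timelines")
      out[[length(out) + 1]] <- data.frame(
        target_cf = tcf, masker_cf = mcf, level = lv,
        correlation = cor(as.vector(alone), as.vector(both)))
    }
  }
  do.call(rbind, out)
}
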