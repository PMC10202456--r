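#' Normalized covariance between two equally shaped matrices
#'
#' The ratio of the covariance between the entries of `a` and `b` and the
#' square root of the product of their variances (a correlation computed
#' over all entries). This is the variance-explained statistic used
#' throughout the manifold analyses; a conventional R-squared variant is
#' available from the variance-explained functions.
#'
#' @param a,b numeric matrices of equal shape.
#' @return scalar in \[-1, 1\].
#' @export
normalized_covariance <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  cor(as.vector(a), as.vector(b))
}

#' Signal/noise decomposition of paired repeat recordings
#'
#' Given two repeats of identical stimulation, the per-unit signal variance
#' is the cross-trial covariance, the total variance is the average of the
#' two single-trial variances, and the noise variance is their difference
#' (additive by construction). Pairwise correlations are decomposed the same
#' way: total, signal, and noise covariances are all normalized by the total
#' variances, so signal + noise correlation equals total correlation.
#'
#' @param rec1,rec2 units x bins count matrices (equal shapes).
#' @return list with per-unit `total_var`, `signal_var`, `noise_var` and
#'   unit-pair matrices `total_corr`, `signal_corr`, `noise_corr`
#'   (zero-variance units give NA rows/columns).
#' @export
signal_noise_stats <- function(rec1, rec2) {
  stopifnot(all(dim(rec1) == dim(rec2)))
  c11 <- cov(t(rec1)); c22 <- cov(t(rec2))
  c12 <- cov(t(rec1), t(rec2))
  S <- (c12 + t(c12)) / 2
  Tt <- (c11 + c22) / 2
  N <- Tt - S
  tv <- diag(Tt)
  denom <- sqrt(outer(tv, tv))
  denom[denom == 0] <- NA
  list(total_var = tv, signal_var = diag(S), noise_var = diag(N),
       total_corr = Tt / denom, signal_corr = S / denom,
       noise_corr = N / denom)
}

#' Fit principal components of population activity
#'
#' PCA on the units x bins training matrix after subtracting each unit's
#' mean. Components are ordered by explained variance, descending; the
#' projection matrix has orthonormal rows.
#'
#' @param Rtrain units x bins matrix.
#' @param D optional number of components to retain (default: full rank).
#' @return an object of class `pc_basis` with `Z` (D x M projection matrix),
#'   `unit_means`, and `eig` (component variances).
#' @export
fit_pcs <- function(Rtrain, D = NULL) {
  M <- nrow(Rtrain)
  if (ncol(Rtrain) <= M)
    warning("fewer time bins than units: PCA is rank deficient")
  p <- prcomp(t(Rtrain), center = TRUE, scale. = FALSE)
  keep <- if (is.null(D)) seq_along(p$sdev) else seq_len(min(D, ncol(p$rotation)))
  rot <- p$rotation
  dimnames(rot) <- NULL
  structure(list(Z = t(rot[, keep, drop = FALSE]),
                 unit_means = as.numeric(p$center),
                 eig = p$sdev[keep]^2),
            class = "pc_basis")
}

#' Project activity onto a fitted PC basis
#'
#' @param R units x bins matrix.
#' @param basis a [fit_pcs()] basis.
#' @param D number of components (default: all in basis).
#' @return D x bins latent trajectory matrix.
#' @export
project_latents <- function(R, basis, D = nrow(basis$Z)) {
  stopifnot(inherits(basis, "pc_basis"))
  basis$Z[seq_len(D), , drop = FALSE] %*% (R - basis$unit_means)
}

reconstruct_from_basis <- function(R, basis, D, add_means = basis$unit_means) {
  X <- project_latents(R, basis, D)
  t(basis$Z[seq_len(D), , drop = FALSE]) %*% X + add_means
}

#' Total variance explained by the leading D PCs
#'
#' Projects the test activity onto the first D training PCs, reconstructs it,
#' and compares reconstruction to original with the normalized-covariance
#' statistic (or a conventional R-squared).
#'
#' @param Rtest1 units x bins test matrix.
#' @param basis a [fit_pcs()] basis (fitted on training data).
#' @param D number of components (0 gives 0).
#' @param statistic `"normcov"` (default) or `"r2"`.
#' @return scalar fraction.
#' @export
total_variance_explained <- function(Rtest1, basis, D,
                                     statistic = c("normcov", "r2")) {
  statistic <- match.arg(statistic)
  if (D == 0) return(0)
  Rhat <- reconstruct_from_basis(Rtest1, basis, D)
  ve_stat(Rtest1, Rhat, statistic)
}

#' Signal variance explained by the leading D PCs
#'
#' Reconstructs activity from the latents of repeat 1 and compares it to the
#' activity of repeat 2 (with repeat 2's unit means restored): only
#' trial-reproducible structure can be explained.
#'
#' @param Rtest1,Rtest2 units x bins matrices from two repeats.
#' @inheritParams total_variance_explained
#' @return scalar fraction.
#' @export
signal_variance_explained <- function(Rtest1, Rtest2, basis, D,
                                      statistic = c("normcov", "r2")) {
  statistic <- match.arg(statistic)
  if (D == 0) return(0)
  X <- project_latents(Rtest1, basis, D)
  Rhat2 <- t(basis$Z[seq_len(D), , drop = FALSE]) %*% X + rowMeans(Rtest2)
  ve_stat(Rtest2, Rhat2, statistic)
}

ve_stat <- function(R, Rhat, statistic) {
  if (statistic == "normcov") return(normalized_covariance(R, Rhat))
  1 - sum((R - Rhat)^2) / sum((R - mean(R))^2)
}

#' Variance-explained curves over the number of components
#'
#' @param Rtest1,Rtest2 test repeat matrices.
#' @param basis a [fit_pcs()] basis.
#' @param Ds component counts (default 1..basis size).
#' @param statistic `"normcov"` or `"r2"`.
#' @return data frame with `D`, `total_ve`, `signal_ve`.
#' @export
variance_explained_curves <- function(Rtest1, Rtest2, basis,
                                      Ds = seq_len(nrow(basis$Z)),
                                      statistic = "normcov") {
  data.frame(
    D = Ds,
    total_ve = vapply(Ds, function(D)
      total_variance_explained(Rtest1, basis, D, statistic), numeric(1)),
    signal_ve = vapply(Ds, function(D)
      signal_variance_explained(Rtest1, Rtest2, basis, D, statistic),
      numeric(1)))
}

#' Signal-manifold dimensionality from a signal-variance curve
#'
#' The smallest number of components whose signal variance explained reaches
#' `criterion` times the curve's plateau (its maximum). Returns NA when the
#' curve has not saturated (still rising by more than 1% of the plateau at
#' its end).
#'
#' @param curve signal-variance-explained values for D = 1, 2, ...
#' @param criterion plateau fraction (default 0.95).
#' @return integer dimensionality, or NA if non-saturating.
#' @export
signal_dimensionality <- function(curve, criterion = 0.95) {
  plateau <- max(curve)
  n <- length(curve)
  if (n >= 2 && (curve[n] - curve[n - 1]) > 0.01 * abs(plateau))
    return(NA_integer_)
  as.integer(which(curve >= criterion * plateau)[1])
}

#' Per-PC signal fraction
#'
#' For each component, the cross-trial covariance of the two repeats'
#' projections relative to their average projection variance: the share of
#' that component's variance that is signal rather than noise.
#'
#' @param Rtest1,Rtest2 repeat matrices.
#' @param basis a [fit_pcs()] basis.
#' @return numeric vector (one value per PC, NA for zero-variance
#'   projections).
#' @export
per_pc_signal_fraction <- function(Rtest1, Rtest2, basis) {
  X1 <- project_latents(Rtest1, basis)
  X2 <- project_latents(Rtest2, basis)
  vapply(seq_len(nrow(X1)), function(d) {
    v1 <- var(X1[d, ]); v2 <- var(X2[d, ])
    if (v1 == 0 || v2 == 0) return(NA_real_)
    cov(X1[d, ], X2[d, ]) / ((v1 + v2) / 2)
  }, numeric(1))
}

#' Similarity of signal dynamics between two animals
#'
#' Variance in `Y` explained by ordinary least-squares regression of `Y`
#' onto `X` (with intercept), pooled over dimensions: 1 - SSE/SST. Computed
#' in-sample by default; set `split` to fit on the first half of the
#' timeline and evaluate on the second.
#'
#' @param X,Y D x T latent-trajectory matrices over the same stimulus
#'   timeline (equal T).
#' @param split logical; use a train/test split of the regression.
#' @return fraction of variance explained.
#' @export
cross_animal_similarity <- function(X, Y, split = FALSE) {
  stopifnot(ncol(X) == ncol(Y))
  T_ <- ncol(X)
  if (T_ <= nrow(X)) stop("need more time bins than dimensions")
  design <- cbind(1, t(X))
  resp <- t(Y)
  if (!split) {
    fit <- lm.fit(design, resp)
    sse <- sum(fit$residuals^2)
    sst <- sum(scale(resp, scale = FALSE)^2)
  } else {
    i1 <- seq_len(floor(T_ / 2)); i2 <- setdiff(seq_len(T_), i1)
    fit <- lm.fit(design[i1, , drop = FALSE], resp[i1, , drop = FALSE])
    pred <- design[i2, , drop = FALSE] %*% fit$coefficients
    sse <- sum((resp[i2, , drop = FALSE] - pred)^2)
    sst <- sum(scale(resp[i2, , drop = FALSE], scale = FALSE)^2)
  }
  1 - sse / sst
}
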