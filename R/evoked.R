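#' Extract onset-subtracted evoked responses
#'
#' For each stimulus, the 25-ms post-onset segment of the layer-4 (or given)
#' channel is extracted at the native 0.5-ms sampling (50 samples at 2 kHz)
#' and the value at onset is subtracted, so the first sample of every row is
#' exactly zero.
#'
#' @param rec an [lfp_recording()].
#' @param channel channel index; typically `layer_map$l4_center`.
#' @param window response window in seconds (default `c(0, 0.025)`).
#' @return List of class `evoked_matrix`: `Y` (trials x samples, mV),
#'   `trial_ids`, `channel`, `fs`. Trials whose window would run past the
#'   end of the recording are dropped with a message.
#' @export
extract_evoked <- function(rec, channel, window = c(0, 0.025)) {
  fs <- rec$fs
  n_e <- as.integer(round(diff(window) * fs))
  x <- rec$lfp[channel, ]
  onsets <- rec$stim_table$onset_s
  keep <- logical(length(onsets))
  Y <- matrix(NA_real_, length(onsets), n_e)
  for (i in seq_along(onsets)) {
    idx <- window_samples(onsets[i] + window[1], onsets[i] + window[2], fs)
    if (idx[length(idx)] > length(x)) next
    Y[i, ] <- x[idx] - x[idx[1]]
    keep[i] <- TRUE
  }
  if (any(!keep))
    message(sum(!keep), " trial(s) dropped: onset too close to recording end")
  structure(list(Y = Y[keep, , drop = FALSE],
                 trial_ids = which(keep), channel = channel, fs = fs),
            class = "evoked_matrix")
}

#' Principal-component basis of the evoked responses
#'
#' The mean response `xi0` is the trial average; the components `xi_k` are
#' the leading eigenvectors of the cross-trial covariance of the centered
#' responses. Each component is oriented so that its dot product with `xi0`
#' is non-negative (when that dot product is numerically zero, the
#' largest-magnitude element is made positive), removing the eigenvector
#' sign ambiguity that would otherwise flip quintile order between runs.
#'
#' @param Y an `evoked_matrix` or a trials x samples matrix (>= 10 trials).
#' @param n_components number of retained components (default 2).
#' @return List of class `evoked_basis`: `xi0`, `components` (samples x
#'   n_components, orthonormal columns), `weights` (trials x n_components,
#'   zero mean per column), `eigenvalues` (variance per mode, all modes),
#'   `ve_continuous` (fraction of cross-trial variance captured by the
#'   retained components).
#' @export
fit_evoked_pca <- function(Y, n_components = 2) {
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  if (nrow(Y) < 10) stop("fit_evoked_pca needs at least 10 trials")
  xi0 <- colMeans(Y)
  C <- sweep(Y, 2, xi0)
  total_var <- sum(C^2)
  if (total_var < .Machine$double.eps * nrow(Y))
    stop("degenerate evoked matrix: zero cross-trial variance, ",
         "variance explained is undefined")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  comps <- pc$rotation[, seq_len(n_components), drop = FALSE]
  w <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    d <- sum(comps[, k] * xi0)
    flip <- if (abs(d) > 1e-10 * sqrt(sum(xi0^2))) d < 0
            else comps[which.max(abs(comps[, k])), k] < 0
    if (flip) {
      comps[, k] <- -comps[, k]
      w[, k] <- -w[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(xi0 = xi0, components = comps, weights = w,
                 eigenvalues = ev,
                 ve_continuous = sum(ev[seq_len(n_components)]) / sum(ev)),
            class = "evoked_basis")
}

# Rank-based equipartition into `n_groups` labels (1 = smallest weight).
# Stable: ties broken by trial order, so group sizes differ by at most 1.
.quintile_labels <- function(w, n_groups = 5) {
  n <- length(w)
  r <- rank(w, ties.method = "first")
  cuts <- floor(n * (0:n_groups) / n_groups)
  findInterval(r, cuts[-1], left.open = TRUE) + 1L
}

#' Quintile discretization of PC weights
#'
#' Per component, trials are rank-partitioned into five equal groups
#' (labels 1-5 ordered by weight) and each group is represented by the mean
#' weight of its members. `ve_discrete` is the fraction of total cross-trial
#' variance captured when every trial is reconstructed from its
#' quintile-average weights; it can never exceed `ve_continuous`.
#'
#' @param basis an `evoked_basis`.
#' @param Y optional trials x samples matrix on which `ve_discrete` is
#'   evaluated (defaults to reconstructing the variance from the basis
#'   weights themselves).
#' @return List of class `quintile_scheme`: per-component `labels` (trials x
#'   n_components integer matrix), `group_means` (5 x n_components),
#'   `boundaries` (weight values at the group edges), `ve_discrete`.
#' @export
discretize_weights <- function(basis, Y = NULL) {
  w <- basis$weights
  n <- nrow(w)
  if (n < 5) stop("discretize_weights needs at least 5 trials")
  nc <- ncol(w)
  labels <- matrix(0L, n, nc)
  gm <- matrix(0, 5, nc)
  bounds <- matrix(NA_real_, 4, nc)
  for (k in seq_len(nc)) {
    labels[, k] <- .quintile_labels(w[, k])
    gm[, k] <- vapply(1:5, function(g) mean(w[labels[, k] == g, k]),
                      numeric(1))
    sw <- sort(w[, k])
    cuts <- floor(n * (1:4) / 5)
    bounds[, k] <- (sw[cuts] + sw[cuts + 1]) / 2
  }
  what <- gm[cbind(as.vector(labels), rep(seq_len(nc), each = n))]
  what <- matrix(what, n, nc)
  if (is.null(Y)) {
    # residual variance = continuous residual + within-group weight spread
    tot <- sum(basis$eigenvalues) * (n - 1)
    resid <- tot * (1 - basis$ve_continuous) + sum((w - what)^2)
    ve_d <- 1 - resid / tot
  } else {
    if (inherits(Y, "evoked_matrix")) Y <- Y$Y
    yhat <- reconstruct_evoked(basis, weights = what)
    ve_d <- compute_fve(Y, yhat)
  }
  structure(list(labels = labels, group_means = gm, boundaries = bounds,
                 ve_discrete = ve_d),
            class = "quintile_scheme")
}

#' Reconstruct evoked responses from weights or quintile labels
#'
#' `yhat_i = xi0 + sum_k alpha_hat_{ik} xi_k`, where `alpha_hat` is either
#' the continuous weight or, for label input, the quintile-average weight
#' of the trial's group.
#'
#' @param basis an `evoked_basis`.
#' @param labels trials x n_components integer matrix of labels in 1..5
#'   (requires `scheme`).
#' @param weights trials x n_components numeric matrix of continuous
#'   weights (alternative to `labels`).
#' @param scheme a `quintile_scheme` supplying the group-mean weights.
#' @return trials x samples matrix of predicted responses.
#' @export
reconstruct_evoked <- function(basis, labels = NULL, weights = NULL,
                               scheme = NULL) {
  if (is.null(weights)) {
    if (is.null(labels) || is.null(scheme))
      stop("provide either `weights` or both `labels` and `scheme`")
    labels <- as.matrix(labels)
    if (any(labels < 1 | labels > 5))
      stop("labels must be in 1..5")
    nc <- ncol(labels)
    weights <- matrix(0, nrow(labels), nc)
    for (k in seq_len(nc))
      weights[, k] <- scheme$group_means[labels[, k], k]
  }
  weights <- as.matrix(weights)
  nc <- ncol(weights)
  t(basis$xi0 + basis$components[, seq_len(nc), drop = FALSE] %*% t(weights))
}

#' Fraction of variance explained
#'
#' `1 - sum_i |y_i - yhat_i|^2 / sum_i |y_i - ybar|^2`, summed over the
#' response window, with `ybar` the mean of `Y` itself (the test-set mean
#' when applied to held-out trials).
#'
#' @param Y trials x samples matrix of observed responses.
#' @param Yhat matching matrix of predictions.
#' @return Scalar fVE (1 for perfect prediction, 0 for predicting the mean).
#' @export
compute_fve <- function(Y, Yhat) {
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat shapes differ")
  denom <- sum(sweep(Y, 2, colMeans(Y))^2)
  if (denom == 0) stop("zero cross-trial variance: fVE undefined")
  1 - sum((Y - Yhat)^2) / denom
}
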