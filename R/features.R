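#' Configuration of the pre-stimulus feature set
#'
#' @param channel_set channel indices used as classifier inputs (a single
#'   channel, a pair, or the channels feeding the spatial-PC variant).
#' @param l_band low-frequency band (Hz) for the power-ratio numerator;
#'   must lie inside `w_band`.
#' @param w_band wide normalization band (Hz); fixed at (1, 50) in the
#'   reference analysis.
#' @param activation_window length of the instantaneous-activation window
#'   in ms (mean over the last `activation_window` ms before t0).
#' @param baseline_window baseline window in ms relative to t0.
#' @param psd_window periodogram window length in seconds.
#' @param n_spatial_modes cap on retained spatial PCA modes (<= 3).
#' @return List of class `feature_config`.
#' @export
feature_config <- function(channel_set = NULL,
                           l_band = c(1, 5),
                           w_band = c(1, 50),
                           activation_window = 10,
                           baseline_window = c(-1000, -200),
                           psd_window = 2,
                           n_spatial_modes = 3) {
  if (l_band[1] < w_band[1] || l_band[2] > w_band[2])
    stop("l_band must be contained in w_band")
  if (n_spatial_modes > 3) stop("n_spatial_modes must be <= 3")
  structure(as.list(environment()), class = "feature_config")
}

#' LFP activation at a time point
#'
#' Mean of the trace over the `activation_window` (default 10 ms) ending at
#' `t0`, minus the mean over the baseline window (default -1000 to -200 ms).
#' A proxy for the instantaneous ongoing depolarization level; linear in
#' the input trace.
#'
#' @param x single-channel trace (mV).
#' @param t0 reference time in seconds (stimulus onset); vectorized.
#' @param fs sampling rate, Hz.
#' @param cfg a [feature_config()].
#' @return Activation in mV, one value per `t0`.
#' @export
compute_activation <- function(x, t0, fs, cfg = feature_config()) {
  b <- cfg$baseline_window / 1000
  a_len <- cfg$activation_window / 1000
  if (any(t0 + b[1] < 0))
    stop("insufficient history before t0 for the activation baseline")
  vapply(t0, function(tt) {
    recent <- window_samples(tt - a_len, tt, fs)
    basel <- window_samples(tt + b[1], tt + b[2], fs)
    mean(x[recent]) - mean(x[basel])
  }, numeric(1))
}

#' One-sided FFT periodogram
#'
#' Rectangular window, mean removal only. With the default 2-s window the
#' bin width is 0.5 Hz.
#'
#' @param x signal segment.
#' @param fs sampling rate, Hz.
#' @return data.frame with `freq` (Hz, positive bins) and `power`.
#' @export
periodogram_psd <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  half <- floor(n / 2)
  data.frame(freq = (1:half) * fs / n,
             power = (Mod(X[2:(half + 1)])^2) / n)
}

#' Low-frequency power ratio
#'
#' Periodogram area over the L band divided by the area over the W band
#' (band sums include both endpoints), computed on the `psd_window` seconds
#' preceding `t0`. Invariant to amplitude rescaling of the trace; in
#' `[0, 1]` whenever the L band lies inside the W band.
#'
#' @inheritParams compute_activation
#' @return Power ratio in `[0, 1]`, one value per `t0`.
#' @export
compute_power_ratio <- function(x, t0, fs, cfg = feature_config()) {
  if (cfg$l_band[1] < cfg$w_band[1] || cfg$l_band[2] > cfg$w_band[2])
    stop("l_band must be contained in w_band")
  if (any(t0 < cfg$psd_window))
    stop("insufficient history before t0 for the PSD window")
  vapply(t0, function(tt) {
    idx <- window_samples(tt - cfg$psd_window, tt, fs)
    p <- periodogram_psd(x[idx], fs)
    num <- sum(p$power[p$freq >= cfg$l_band[1] & p$freq <= cfg$l_band[2]])
    den <- sum(p$power[p$freq >= cfg$w_band[1] & p$freq <= cfg$w_band[2]])
    if (den == 0) return(0)
    num / den
  }, numeric(1))
}

#' Trial-locked feature table
#'
#' Computes activation and power ratio for every stimulus onset on each
#' channel in `cfg$channel_set` (power ratio on the first listed channel
#' only, matching the pair-classifier convention).
#'
#' @param rec an [lfp_recording()].
#' @param cfg a [feature_config()]; `channel_set` defaults to the first
#'   good channel.
#' @return data.frame with `trial`, one `activation_ch<i>` column per
#'   channel, and `power_ratio`.
#' @export
trial_features <- function(rec, cfg = feature_config()) {
  chans <- cfg$channel_set
  if (is.null(chans)) chans <- which(rec$channel_mask)[1]
  t0 <- rec$stim_table$onset_s
  out <- data.frame(trial = seq_along(t0))
  for (ci in chans)
    out[[paste0("activation_ch", ci)]] <-
      compute_activation(rec$lfp[ci, ], t0, rec$fs, cfg)
  out$power_ratio <- compute_power_ratio(rec$lfp[chans[1], ], t0, rec$fs, cfg)
  out
}

#' Spatial-PC multichannel features
#'
#' Fits a spatial PCA to the multichannel LFP during spontaneous epochs
#' (all samples outside `exclude_s` of any stimulus onset), retains up to
#' `n_spatial_modes` modes or however many explain more than 95% of the
#' spatial variance (whichever is fewer), and returns the pre-stimulus
#' activation of each mode's projection together with the power ratio of
#' the first mode.
#'
#' @param rec an [lfp_recording()].
#' @param t0 stimulus onsets (s).
#' @param cfg a [feature_config()].
#' @param exclude_s half-width of the peri-stimulus exclusion zone (s) used
#'   when fitting the spatial modes.
#' @return List with `features` (data.frame: per-mode activation columns and
#'   `power_ratio`), `modes` (channels x retained modes), `n_modes`.
#' @export
compute_spatial_pc_features <- function(rec, t0, cfg = feature_config(),
                                        exclude_s = 0.5) {
  good <- which(rec$channel_mask)
  if (length(good) < 2) stop("spatial PCA needs at least 2 good channels")
  n <- ncol(rec$lfp)
  keep <- rep(TRUE, n)
  for (on in rec$stim_table$onset_s) {
    idx <- window_samples(max(0, on - exclude_s), min(n / rec$fs, on + exclude_s),
                          rec$fs)
    keep[idx[idx >= 1 & idx <= n]] <- FALSE
  }
  X <- t(rec$lfp[good, keep, drop = FALSE])     # samples x channels
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_modes <- as.integer(min(cfg$n_spatial_modes, which(ve > 0.95)[1],
                            length(good)))
  modes <- pc$rotation[, seq_len(n_modes), drop = FALSE]
  proj <- t(modes) %*% rec$lfp[good, , drop = FALSE]  # modes x samples
  feats <- data.frame(trial = seq_along(t0))
  for (m in seq_len(n_modes))
    feats[[paste0("activation_pc", m)]] <-
      compute_activation(proj[m, ], t0, rec$fs, cfg)
  feats$power_ratio <- compute_power_ratio(proj[1, ], t0, rec$fs, cfg)
  list(features = feats, modes = modes, n_modes = n_modes)
}

#' Sliding-window feature series
#'
#' Recomputes activation and power ratio on trailing windows every `step`
#' ms, for continuous state classification. Values are piecewise constant
#' between updates. No output is produced before one full PSD window plus
#' the activation baseline has elapsed.
#'
#' @param x single-channel trace.
#' @param fs sampling rate, Hz.
#' @param step update step in ms (default 5; must be at least one sample).
#' @param cfg a [feature_config()].
#' @return data.frame with `time_s` (update times), `activation`,
#'   `power_ratio`. Trial-locked features equal this series evaluated at
#'   the stimulus onsets.
#' @export
sliding_features <- function(x, fs, step = 5, cfg = feature_config()) {
  if (step < 1000 / fs) stop("step must be at least one sample period")
  n <- length(x)
  warm <- max(cfg$psd_window, -cfg$baseline_window[1] / 1000)
  times <- seq(warm, (n - 1) / fs, by = step / 1000)
  if (!length(times)) stop("trace shorter than the PSD window")

  # activation via cumulative sums (exact window means, O(1) per update)
  cs <- c(0, cumsum(x))
  wmean <- function(t_lo, t_hi) {
    i0 <- time_to_sample(t_lo, fs)
    m <- as.integer(round((t_hi - t_lo) * fs))
    (cs[i0 + m] - cs[i0]) / m
  }
  a_len <- cfg$activation_window / 1000
  b <- cfg$baseline_window / 1000
  activation <- wmean(times - a_len, times) - wmean(times + b[1], times + b[2])

  nw <- as.integer(round(cfg$psd_window * fs))
  half <- floor(nw / 2)
  freq <- (1:half) * fs / nw
  li <- which(freq >= cfg$l_band[1] & freq <= cfg$l_band[2])
  wi <- which(freq >= cfg$w_band[1] & freq <= cfg$w_band[2])
  lo <- min(c(li, wi)); hi <- max(c(li, wi))
  power_ratio <- vapply(times, function(tt) {
    idx <- window_samples(tt - cfg$psd_window, tt, fs)
    seg <- x[idx]
    X <- stats::fft(seg - mean(seg))[(lo + 1):(hi + 1)]
    p <- Mod(X)^2
    num <- sum(p[li - lo + 1])
    den <- sum(p[wi - lo + 1])
    if (den == 0) 0 else num / den
  }, numeric(1))
  data.frame(time_s = times, activation = activation,
             power_ratio = power_ratio)
}
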