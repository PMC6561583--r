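#' Anti-aliased downsampling of a recording
#'
#' Decimates the LFP to `target_fs` after a zero-phase 8th-order Butterworth
#' low-pass at `0.4 * target_fs` (applied forward and backward, so no phase
#' distortion of evoked latencies). Stimulus onsets are expressed in seconds
#' and are unchanged. If the recording is already at `target_fs` the input
#' is returned untouched.
#'
#' @param rec an [lfp_recording()].
#' @param target_fs target sampling rate in Hz; must divide `rec$fs`.
#' @return The decimated `lfp_recording` (sample count `floor(n * target_fs
#'   / fs)`).
#' @export
downsample_recording <- function(rec, target_fs = 2000) {
  if (target_fs > rec$fs) stop("target_fs exceeds the recording rate")
  if (target_fs == rec$fs) return(rec)
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("target_fs must divide the recording sampling rate")
  factor <- as.integer(round(factor))
  bf <- signal::butter(8, 0.4 * target_fs / (rec$fs / 2), type = "low")
  n_out <- floor(ncol(rec$lfp) / factor)
  keep <- seq.int(1L, by = factor, length.out = n_out)
  out <- matrix(0, nrow(rec$lfp), n_out)
  for (c_i in seq_len(nrow(rec$lfp))) {
    filtered <- signal::filtfilt(bf, rec$lfp[c_i, ])
    out[c_i, ] <- filtered[keep]
  }
  rec$lfp <- out
  rec$fs <- target_fs
  # drop stimuli that no longer fit (trailing partial block)
  dur <- rec_duration(rec)
  rec$stim_table <- rec$stim_table[rec$stim_table$onset_s < dur, ]
  validate_recording(rec)
}

#' Remove mains interference by harmonic regression
#'
#' For each trial, the phase and amplitude of sinusoids at 60, 120, ...,
#' 300 Hz are fit by least squares over a 500-ms pre-stimulus window and
#' the fitted sinusoids, extrapolated over the peri-stimulus window, are
#' subtracted. With `per_trial = FALSE` a single fit over the whole
#' recording is subtracted everywhere.
#'
#' @param rec an [lfp_recording()].
#' @param fit_window length-2 vector, window relative to each onset (s)
#'   used for the fit; must be 500 ms long and end at or before the onset.
#' @param subtract_until end of the subtraction window relative to onset, s.
#' @param harmonics frequencies to fit, Hz.
#' @param per_trial fit per trial (default) or once for the recording.
#' @return The cleaned `lfp_recording`.
#' @export
remove_line_noise <- function(rec, fit_window = c(-0.55, -0.05),
                              subtract_until = 0.3,
                              harmonics = seq(60, 300, by = 60),
                              per_trial = TRUE) {
  if (!per_trial) {
    n <- ncol(rec$lfp)
    X <- .harmonic_design((seq_len(n) - 1) / rec$fs, harmonics)
    for (c_i in seq_len(nrow(rec$lfp))) {
      fit <- stats::lm.fit(X, rec$lfp[c_i, ])
      rec$lfp[c_i, ] <- rec$lfp[c_i, ] - X[, -1, drop = FALSE] %*%
        fit$coefficients[-1]
    }
    return(rec)
  }
  if (abs(diff(fit_window) - 0.5) > 1e-9)
    stop("fit_window must be 500 ms long")
  if (fit_window[2] > 0)
    stop("fit_window overlaps the evoked window: it must end at or before onset")
  for (i in seq_len(nrow(rec$stim_table))) {
    t0 <- rec$stim_table$onset_s[i]
    fit_idx <- window_samples(t0 + fit_window[1], t0 + fit_window[2], rec$fs)
    sub_idx <- window_samples(t0 + fit_window[1], t0 + subtract_until, rec$fs)
    sub_idx <- sub_idx[sub_idx <= ncol(rec$lfp)]
    if (fit_idx[1] < 1) next
    t_fit <- (fit_idx - 1) / rec$fs
    t_sub <- (sub_idx - 1) / rec$fs
    Xf <- .harmonic_design(t_fit, harmonics)
    Xs <- .harmonic_design(t_sub, harmonics)
    for (c_i in seq_len(nrow(rec$lfp))) {
      beta <- stats::lm.fit(Xf, rec$lfp[c_i, fit_idx])$coefficients
      rec$lfp[c_i, sub_idx] <- rec$lfp[c_i, sub_idx] -
        Xs[, -1, drop = FALSE] %*% beta[-1]
    }
  }
  rec
}

.harmonic_design <- function(t, harmonics) {
  cols <- lapply(harmonics, function(f)
    cbind(sin(2 * pi * f * t), cos(2 * pi * f * t)))
  cbind(1, do.call(cbind, cols))
}

#' Flag channels with slow, irregular drift
#'
#' A channel is masked when its sub-0.5-Hz power or its moving-baseline
#' excursion (range of a 10-s moving average) exceeds `k` times the
#' cross-channel median of that statistic. Requires at least 60 s of data.
#'
#' @param rec an [lfp_recording()].
#' @param k multiplier on the cross-channel median (default 5).
#' @return Logical vector of good channels (`TRUE` = keep). If more than
#'   half the channels would be masked, a warning reports the count.
#' @export
flag_bad_channels <- function(rec, k = 5) {
  n <- ncol(rec$lfp)
  if (n / rec$fs < 60)
    stop("flag_bad_channels needs at least 60 s of data")
  nc <- nrow(rec$lfp)
  low_power <- numeric(nc)
  excursion <- numeric(nc)
  win <- as.integer(10 * rec$fs)
  for (c_i in seq_len(nc)) {
    x <- rec$lfp[c_i, ] - mean(rec$lfp[c_i, ])
    P <- Mod(stats::fft(x))^2 / n
    f <- (seq_len(n) - 1) * rec$fs / n
    low_power[c_i] <- sum(P[f > 0 & f < 0.5])
    cs <- c(0, cumsum(x))
    ma <- (cs[(win + 1):(n + 1)] - cs[1:(n - win + 1)]) / win
    excursion[c_i] <- diff(range(ma))
  }
  bad <- low_power > k * stats::median(low_power) |
    excursion > k * stats::median(excursion)
  if (sum(bad) > nc / 2)
    warning(sum(bad), " of ", nc, " channels flagged as drifting; ",
            "check the recording before masking")
  !bad
}
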