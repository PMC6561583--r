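#' Configuration for the synthetic laminar recording generator
#'
#' Defaults emulate an awake-mouse barrel-cortex laminar recording: a
#' 32-channel probe at 25-um spacing, LFP at 2 kHz, ~400 whisker stimuli
#' with pseudo-random 2-3 s inter-stimulus intervals, a layer-4 evoked dip
#' of about -0.81 mV with cross-trial SD of about 0.45 mV, and ongoing
#' activity whose low-frequency oscillation amplitude and slow mean level
#' are driven by a single latent "state" process. The couplings reproduce
#' the negative interaction seen in cortex: trials preceded by negative LFP
#' activation carry smaller evoked responses.
#'
#' @param n_channels number of probe channels.
#' @param channel_spacing contact spacing in micrometers.
#' @param fs sampling rate, Hz (>= 2000).
#' @param duration recording length in seconds, or `NULL` to fit `n_trials`.
#' @param n_trials number of stimuli.
#' @param isi_range inter-stimulus interval bounds in seconds.
#' @param template_peak_mV evoked dip amplitude (negative, mV).
#' @param template_peak_time time of the dip in ms after stimulus onset.
#' @param template_width temporal dilation of the template in ms; the
#'   default equals `template_peak_time` (dilation factor 1).
#' @param depth_profile_center channel index of the simulated layer-4
#'   center, where the evoked depth profile peaks.
#' @param state_process list with `type` (`"ou"` for Ornstein-Uhlenbeck or
#'   `"markov"` for a 2-state telegraph process) and `timescale` in seconds.
#' @param osc_freq frequency of the state-modulated oscillation, Hz.
#' @param osc_amp_by_state oscillation amplitude (mV) in the desynchronized
#'   and synchronized extremes; for the Markov process, the two states.
#' @param broadband_exponent slope beta of the 1/f^beta broadband floor.
#' @param broadband_sd broadband standard deviation at the profile peak, mV.
#' @param activation_drift_sd SD of the slow state-driven mean shift, mV.
#' @param sensor_noise_sd per-channel independent white noise SD, mV.
#' @param coupling_activation evoked-amplitude change (mV) per mV of true
#'   pre-stimulus activation. Negative: depolarized (negative-activation)
#'   epochs yield smaller dips.
#' @param coupling_powerratio amplitude change (mV) per unit of the latent
#'   synchronization level (centered at 0.5).
#' @param width_coupling relative width change per unit latent state.
#' @param amp_noise_sd SD of per-trial amplitude variability not explained
#'   by the latent state, mV.
#' @param width_noise_sd SD of unexplained per-trial width variability.
#' @param latency_jitter_ms SD of the per-trial response latency jitter in
#'   ms; contributes trial-to-trial evoked shape variability beyond the
#'   leading components without adding ongoing background power.
#' @param amp_floor_mV largest (least negative) allowed evoked amplitude:
#'   even in the most desynchronized epochs a punctate deflection evokes a
#'   visible dip, so the amplitude distribution's upper tail is truncated
#'   here. Set to 0 to disable (polarity clamp only).
#' @param line_noise_amp amplitude of an optional 60-Hz mains component
#'   (with a weaker 180-Hz harmonic), mV; 0 disables it.
#' @param common_profile optional explicit per-channel gain vector for the
#'   ongoing (state-carrying) signal; default is a Gaussian depth profile
#'   centered on `depth_profile_center` (SD 6 contacts, peak 1).
#' @param evoked_profile optional explicit per-channel gain for the evoked
#'   response; default Gaussian (SD 3 contacts, peak 1 at the L4 center).
#' @param seed integer seed; the generator is fully deterministic given the
#'   config (the seed is part of it).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_channels = 32L,
                             channel_spacing = 25,
                             fs = 2000,
                             duration = NULL,
                             n_trials = 400L,
                             isi_range = c(2, 3),
                             template_peak_mV = -0.81,
                             template_peak_time = 7.5,
                             template_width = 7.5,
                             depth_profile_center = 16L,
                             state_process = list(type = "ou", timescale = 1),
                             osc_freq = 3,
                             osc_amp_by_state = c(0.05, 0.40),
                             broadband_exponent = 1,
                             broadband_sd = 0.075,
                             activation_drift_sd = 0.42,
                             sensor_noise_sd = 0.02,
                             coupling_activation = -1.1,
                             coupling_powerratio = -0.6,
                             width_coupling = 0.20,
                             amp_noise_sd = 0.26,
                             width_noise_sd = 0.06,
                             latency_jitter_ms = 1.0,
                             amp_floor_mV = -0.30,
                             line_noise_amp = 0,
                             common_profile = NULL,
                             evoked_profile = NULL,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (fs < 2000) stop("fs must be at least 2 kHz")
  if (length(isi_range) != 2 || isi_range[1] > isi_range[2])
    stop("isi_range must be (low, high) with low <= high")
  if (!state_process$type %in% c("ou", "markov"))
    stop("state_process$type must be 'ou' or 'markov'")
  if (template_width <= 0) stop("template_width must be positive")
  if (depth_profile_center < 1 || depth_profile_center > n_channels)
    stop("depth_profile_center must be a valid channel index")
  class(cfg) <- "generator_config"
  cfg
}

#' Canonical biphasic evoked-response template
#'
#' A smooth waveform anchored at zero for `t = 0`, with its most negative
#' excursion (the layer-4 dip) near `peak_time` ms and a small late positive
#' rebound. `amp_scale` multiplies the amplitude; `width_scale` dilates
#' time, so the argmin moves proportionally.
#'
#' @param t time in ms (vectorized); typically `[0, 25]`.
#' @param width_scale temporal dilation (> 0).
#' @param amp_scale amplitude multiplier; the dip reaches
#'   `amp_scale * peak_mV`.
#' @param peak_mV dip amplitude at scale 1 (negative, mV).
#' @param peak_time dip latency at scale 1, ms.
#' @return Template values in mV.
#' @export
evoked_template <- function(t, width_scale = 1, amp_scale = 1,
                            peak_mV = -0.81, peak_time = 7.5) {
  if (any(width_scale <= 0)) stop("width_scale must be positive")
  u <- (t / width_scale) / peak_time
  u[u < 0] <- 0
  # main dip: u^2 exp(1 - u^2) peaks at 1 for u = 1
  dip <- u^2 * exp(1 - u^2)
  # late rebound, ~12% of the dip, centered near 2.8x the dip latency
  v <- u / 2.8
  reb <- 0.12 * v^2 * exp(1 - v^2)
  # renormalize so the most negative value is exactly peak_mV at scale 1
  shape <- -dip + reb
  amp_scale * peak_mV * (shape / .template_shape_min())
}

# minimum (most negative) of the unscaled shape, cached at load
.template_shape_cache <- new.env(parent = emptyenv())
.template_shape_min <- function() {
  if (is.null(.template_shape_cache$m)) {
    u <- seq(0, 6, by = 1e-4)
    v <- u / 2.8
    .template_shape_cache$m <- min(-u^2 * exp(1 - u^2) + 0.12 * v^2 * exp(1 - v^2))
  }
  .template_shape_cache$m
}

# Latent scalar state on the full sample grid. Simulated on a 200-Hz grid
# and interpolated (the timescale is ~1 s, far above the grid period).
simulate_state <- function(n_samples, fs, process) {
  fs_c <- 200
  n_c <- ceiling(n_samples / fs * fs_c) + 2L
  tau <- process$timescale
  if (process$type == "ou") {
    a <- exp(-1 / (fs_c * tau))
    innov <- stats::rnorm(n_c, sd = sqrt(1 - a^2))
    z <- as.numeric(stats::filter(innov, a, method = "recursive",
                                  init = stats::rnorm(1)))
  } else {
    flip <- stats::runif(n_c) < 1 / (fs_c * tau)
    z0 <- sample(c(-1, 1), 1)
    z <- z0 * (1 - 2 * (cumsum(flip) %% 2))
  }
  t_c <- (seq_len(n_c) - 1) / fs_c
  t_f <- (seq_len(n_samples) - 1) / fs
  method <- if (process$type == "ou") "linear" else "constant"
  stats::approx(t_c, z, xout = t_f, method = method, rule = 2)$y
}

# 1/f^beta broadband noise by spectral shaping of white noise.
shaped_noise <- function(n, fs, beta, target_sd) {
  if (target_sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)          # two-sided frequency axis
  f[f < 0.5] <- 0.5             # flatten below 0.5 Hz to keep variance finite
  g <- f^(-beta / 2)
  g[1] <- 0                     # remove DC
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x * target_sd / stats::sd(x)
}

# Windowed mean of x over [t0 + a, t0 + b) seconds (vectorized over t0).
.window_mean <- function(x, fs, t0, a, b) {
  vapply(t0, function(tt) {
    idx <- window_samples(tt + a, tt + b, fs)
    mean(x[idx])
  }, numeric(1))
}

#' Generate a synthetic laminar recording with ground truth
#'
#' Ongoing activity is a depth-profiled common signal (1/f^beta broadband +
#' state-modulated oscillation + slow state-driven mean drift) plus
#' independent per-channel sensor noise. At each stimulus onset a biphasic
#' evoked template is injected whose amplitude and width are coupled to the
#' latent state at that moment: the true pre-stimulus activation (computed
#' from the noiseless drift component exactly as the activation feature is
#' defined) shifts the dip amplitude by `coupling_activation` mV per mV, and
#' the latent synchronization level shifts it by `coupling_powerratio` per
#' unit.
#'
#' @param config a [generator_config()].
#' @return A list with elements `recording` (an [lfp_recording()]) and
#'   `ground_truth` (list with `state_trace`, the per-sample latent state,
#'   and `per_trial`, a data.frame of onset times, true activation, true
#'   amplitude in mV, and the amplitude/width scale factors).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  fs <- cfg$fs

  # --- trial packing ---------------------------------------------------
  lead_in <- 3                      # history for 2-s PSD + 1-s baseline
  isis <- stats::runif(cfg$n_trials - 1, cfg$isi_range[1], cfg$isi_range[2])
  onsets <- lead_in + c(0, cumsum(isis))
  needed <- onsets[cfg$n_trials] + 1
  duration <- cfg$duration
  if (is.null(duration)) {
    duration <- ceiling(needed)
  } else if (duration < needed) {
    stop(sprintf(paste0("infeasible trial packing: duration %.1f s cannot ",
                        "hold %d trials with ISI in [%g, %g] s ",
                        "(needs >= %.1f s)"),
         duration, cfg$n_trials, cfg$isi_range[1], cfg$isi_range[2], needed))
  }
  n <- as.integer(round(duration * fs))

  # --- latent state and ongoing components ------------------------------
  z <- simulate_state(n, fs, cfg$state_process)
  sync <- stats::plogis(z)                       # latent synchronization in (0,1)
  osc_amp <- cfg$osc_amp_by_state[1] +
    diff(cfg$osc_amp_by_state) * sync
  tt <- (seq_len(n) - 1) / fs
  osc <- osc_amp * sin(2 * pi * cfg$osc_freq * tt + stats::runif(1, 0, 2 * pi))
  drift <- cfg$activation_drift_sd * z
  broad <- shaped_noise(n, fs, cfg$broadband_exponent, cfg$broadband_sd)
  common <- broad + osc + drift
  if (cfg$line_noise_amp > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    common <- common + cfg$line_noise_amp * sin(2 * pi * 60 * tt + ph[1]) +
      0.3 * cfg$line_noise_amp * sin(2 * pi * 180 * tt + ph[2])
  }

  # --- per-trial ground truth and couplings -----------------------------
  act_true <- .window_mean(drift, fs, onsets, -0.010, 0) -
    .window_mean(drift, fs, onsets, -1.0, -0.2)
  sync_true <- .window_mean(sync, fs, onsets, -2, 0)
  amp_mV <- cfg$template_peak_mV +
    cfg$coupling_activation * act_true +
    cfg$coupling_powerratio * (sync_true - 0.5) +
    cfg$amp_noise_sd * stats::rnorm(cfg$n_trials)
  amp_mV <- pmin(amp_mV, cfg$amp_floor_mV)
  amp_scale <- amp_mV / cfg$template_peak_mV
  z_on <- z[time_to_sample(onsets, fs)]
  width_scale <- 1 + cfg$width_coupling * z_on +
    cfg$width_noise_sd * stats::rnorm(cfg$n_trials)
  width_scale <- pmax(width_scale, 0.4)

  # --- evoked injection (common waveform bank, per-channel profile) -----
  n_ev <- as.integer(round(0.060 * fs))          # 60-ms support
  t_ms <- (seq_len(n_ev) - 1) / fs * 1000
  jitter <- if (cfg$latency_jitter_ms > 0)
    stats::rnorm(cfg$n_trials, sd = cfg$latency_jitter_ms) else
    numeric(cfg$n_trials)
  evoked <- matrix(0, cfg$n_trials, n_ev)
  base_dilation <- cfg$template_width / cfg$template_peak_time
  for (i in seq_len(cfg$n_trials)) {
    evoked[i, ] <- evoked_template(t_ms - jitter[i],
                                   width_scale[i] * base_dilation,
                                   amp_scale[i],
                                   peak_mV = cfg$template_peak_mV,
                                   peak_time = cfg$template_peak_time)
  }
  common_evoked <- numeric(n)
  on_idx <- time_to_sample(onsets, fs)
  for (i in seq_len(cfg$n_trials)) {
    idx <- on_idx[i]:min(on_idx[i] + n_ev - 1L, n)
    common_evoked[idx] <- common_evoked[idx] + evoked[i, seq_along(idx)]
  }

  # --- per-channel assembly --------------------------------------------
  ch <- seq_len(cfg$n_channels)
  prof_common <- cfg$common_profile
  if (is.null(prof_common))
    prof_common <- exp(-(ch - cfg$depth_profile_center)^2 / (2 * 6^2))
  prof_evoked <- cfg$evoked_profile
  if (is.null(prof_evoked))
    prof_evoked <- exp(-(ch - cfg$depth_profile_center)^2 / (2 * 3^2))
  lfp <- tcrossprod(prof_common, common) +
    tcrossprod(prof_evoked, common_evoked)
  if (cfg$sensor_noise_sd > 0)
    lfp <- lfp + matrix(stats::rnorm(length(lfp), sd = cfg$sensor_noise_sd),
                        nrow = cfg$n_channels)

  depths <- (ch - 1) * cfg$channel_spacing
  rec <- lfp_recording(
    lfp, fs = fs, channel_depths = depths,
    stim_table = data.frame(
      onset_s = onsets,
      velocity_deg_s = sample(c(1000, 500, 250, 100), cfg$n_trials,
                              replace = TRUE)),
    meta = list(generator = "lfpstate-synthetic", seed = cfg$seed,
                depth_profile_center = cfg$depth_profile_center))

  gt <- list(
    state_trace = z,
    per_trial = data.frame(
      trial = seq_len(cfg$n_trials),
      onset_s = onsets,
      activation_true_mV = act_true,
      sync_true = sync_true,
      amplitude_mV = amp_mV,
      amp_scale = amp_scale,
      width_scale = width_scale,
      latency_jitter_ms = jitter))
  list(recording = rec, ground_truth = gt)
}

#' Write generator ground truth next to a recording container
#'
#' The per-trial table goes to `<stem>.truth.csv` and the per-sample latent
#' state to `<stem>.state.bin` (float64, little-endian).
#'
#' @param gt the `ground_truth` element returned by [generate_recording()].
#' @param stem container path stem (as for [write_recording()]).
#' @return `stem`, invisibly.
#' @export
write_ground_truth <- function(gt, stem) {
  utils::write.csv(gt$per_trial, paste0(stem, ".truth.csv"),
                   row.names = FALSE)
  con <- file(paste0(stem, ".state.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(gt$state_trace), con, size = 8, endian = "little")
  invisible(stem)
}
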