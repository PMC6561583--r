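# Shared fixtures, built lazily and cached for the whole test session.
.fx <- new.env(parent = emptyenv())

# A moderate synthetic recording with the full classifier chain fitted:
# 8 channels, 120 trials, default couplings and noise.
fx_pipeline <- function() {
  if (is.null(.fx$pipe)) {
    g <- generate_recording(generator_config(
      n_trials = 120L, n_channels = 8L, depth_profile_center = 4L,
      seed = 101L))
    rec <- g$recording
    lmap <- assign_layers(rec)
    ev <- extract_evoked(rec, lmap$l4_center)
    basis <- fit_evoked_pca(ev)
    scheme <- discretize_weights(basis, ev)
    split <- split_trials(nrow(ev$Y), scheme$labels[, 1], seed = 11)
    cfg <- feature_config(channel_set = lmap$l4_center)
    feats <- trial_features(rec, cfg)
    model <- fit_state_classifier(feats, scheme, basis, split, Y = ev$Y)
    report <- evaluate_classifier(model, feats, ev$Y)
    .fx$pipe <- list(g = g, rec = rec, layer_map = lmap, ev = ev,
                     basis = basis, scheme = scheme, split = split,
                     cfg = cfg, feats = feats, model = model,
                     report = report)
  }
  .fx$pipe
}

# Hand-built recording: deterministic multichannel sinusoids, no stimuli
# unless supplied. Depth spacing 25 um.
toy_recording <- function(n_ch = 4, fs = 2000, dur = 10, onsets = numeric(0),
                          trace_fun = NULL) {
  n <- as.integer(dur * fs)
  t <- (seq_len(n) - 1) / fs
  if (is.null(trace_fun))
    trace_fun <- function(ch, t) 0.2 * sin(2 * pi * 3 * t + ch / 10)
  lfp <- t(vapply(seq_len(n_ch), function(ch) trace_fun(ch, t), numeric(n)))
  lfp_recording(lfp, fs = fs, channel_depths = (seq_len(n_ch) - 1) * 25,
                stim_table = data.frame(onset_s = onsets,
                                        velocity_deg_s = rep(NA_real_,
                                                             length(onsets))))
}

# A synthetic score trace object for detector unit tests.
toy_score <- function(s, template_norm2 = 8) {
  structure(list(s = s, template = NULL, template_norm2 = template_norm2),
            class = "score_trace")
}
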