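#' End-to-end state-aware detection pipeline
#'
#' Runs the full chain on one recording: preprocessing (decimation to
#' 2 kHz, optional channel QC), functional layer assignment, evoked
#' extraction and PCA, quintile discretization, pre-stimulus features,
#' classifier fitting and test-set fVE, continuous state classification,
#' matched-filter scoring, state-blind operating point, and constrained
#' state-aware threshold optimization with evaluation on the reserved
#' trials.
#'
#' @param rec an [lfp_recording()] (e.g. from [generate_recording()]).
#' @param seed integer seed for the train/test split and fold assignment.
#' @param optimize_band run the L-band search (slower) and use the selected
#'   band downstream.
#' @param f_lo,f_hi candidate band edges for the search; the pipeline
#'   default is a coarse 17-candidate grid covering 1-45 Hz (the full
#'   [optimize_l_band()] defaults enumerate 80 candidates).
#' @param state_step_ms update step of the continuous state trace.
#' @param qc_channels run [flag_bad_channels()] and mask drifters.
#' @param n_grid threshold-grid resolution for the state-aware
#'   optimization.
#' @param hit_target state-blind hit-rate range defining the operating
#'   point.
#' @return List with the fitted objects (`layer_map`, `basis`, `scheme`,
#'   `model`, `fve_report`, `shuffle`, `state_trace`) and the detection
#'   comparison (`report_blind`, `report_aware`, `comparison`).
#' @export
run_state_pipeline <- function(rec, seed = 1, optimize_band = FALSE,
                               state_step_ms = 10, qc_channels = FALSE,
                               n_grid = 30, hit_target = c(0.80, 0.90),
                               f_lo = c(1, 2, 4, 8),
                               f_hi = c(5, 15, 25, 35, 45)) {
  rec <- downsample_recording(rec, 2000)
  if (qc_channels) rec$channel_mask <- rec$channel_mask & flag_bad_channels(rec)
  lm <- assign_layers(rec)
  ch <- lm$l4_center
  ev <- extract_evoked(rec, ch)
  basis <- fit_evoked_pca(ev)
  scheme <- discretize_weights(basis, ev)
  split <- split_trials(nrow(ev$Y), scheme$labels[, 1], seed)

  cfg <- feature_config(channel_set = ch)
  if (optimize_band) {
    sr <- optimize_l_band(rec, basis, scheme, ev$Y, split, ch,
                          f_lo = f_lo, f_hi = f_hi)
    cfg <- sr$feature_cfg
    model <- sr$model
    feats <- trial_features(rec, cfg)
  } else {
    feats <- trial_features(rec, cfg)
    model <- fit_state_classifier(feats, scheme, basis, split, Y = ev$Y)
  }
  fve_rep <- evaluate_classifier(model, feats, ev$Y)
  shuf <- shuffle_null(model, feats, ev$Y, basis, n_shuffles = 20,
                       seed = seed)

  stt <- compute_state_trace(rec, model, ch, step = state_step_ms,
                             cfg = cfg)
  score <- matched_filter_score(rec$lfp[ch, ], basis$xi0)
  curves_opt <- rate_curves(score, rec, stt,
                            stim_subset = ev$trial_ids[model$split$train])
  curves_eval <- rate_curves(score, rec, stt,
                             stim_subset = ev$trial_ids[model$split$test],
                             peaks = attr(curves_opt, "peaks"))
  op <- choose_operating_point(curves_opt, target = hit_target)
  blind <- state_blind_report(curves_opt, op$theta_blind,
                              eval_curves = curves_eval)
  aware <- optimize_state_thresholds(curves_opt, op$fa_target,
                                     eval_curves = curves_eval,
                                     n_grid = n_grid,
                                     theta_blind = op$theta_blind)
  list(recording = rec, layer_map = lm, evoked = ev, basis = basis,
       scheme = scheme, split = split, features = feats, model = model,
       fve_report = fve_rep, shuffle = shuf, state_trace = stt,
       score = score, operating_point = op,
       report_blind = blind, report_aware = aware,
       comparison = evaluate_observers(blind, aware))
}
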