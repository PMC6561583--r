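#' Optimize the low-frequency band of the power ratio
#'
#' Refits the state classifier for every candidate L band (with W fixed at
#' 1-50 Hz) and selects the band with the best cross-validation fVE; the
#' test split is scored once, for the selected band, and for the 1-5 Hz
#' baseline.
#'
#' @param rec an [lfp_recording()].
#' @param basis an `evoked_basis` for the layer-4 channel.
#' @param scheme the matching `quintile_scheme`.
#' @param Y evoked matrix used for fVE (trials x samples).
#' @param split a `split_record`.
#' @param channel classifier input channel.
#' @param f_lo candidate lower bounds, Hz.
#' @param f_hi candidate upper bounds, Hz (candidates keep `f_hi > f_lo`).
#' @param base_cfg [feature_config()] whose non-band settings (windows,
#'   PSD length) are used for every candidate.
#' @return List of class `search_result`: `candidates` (data.frame with
#'   `f_lo`, `f_hi`, `cv_fve`), `selected` (row index), `test_fve`,
#'   `test_se`, `baseline_fve`, `baseline_se`, `model` (refit on the
#'   selected band).
#' @export
optimize_l_band <- function(rec, basis, scheme, Y, split, channel,
                            f_lo = 1:10, f_hi = seq(5, 45, by = 5),
                            base_cfg = feature_config()) {
  grid <- expand.grid(f_lo = f_lo, f_hi = f_hi)
  grid <- grid[grid$f_hi > grid$f_lo, , drop = FALSE]
  if (!nrow(grid)) stop("empty L-band candidate grid")
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  band_cfg <- function(band) {
    cfg <- base_cfg
    cfg$channel_set <- channel
    cfg$l_band <- band
    cfg
  }
  scores <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- band_cfg(c(grid$f_lo[i], grid$f_hi[i]))
    feats <- trial_features(rec, cfg)
    m <- fit_state_classifier(feats, scheme, basis, split, Y = Y)
    scores[i] <- m$cv_fve
    models[[i]] <- list(model = m, feats = feats, cfg = cfg)
  }
  sel <- which.max(scores)
  rep_sel <- evaluate_classifier(models[[sel]]$model, models[[sel]]$feats, Y)
  base_feats <- trial_features(rec, band_cfg(c(1, 5)))
  base_model <- fit_state_classifier(base_feats, scheme, basis, split, Y = Y)
  rep_base <- evaluate_classifier(base_model, base_feats, Y)
  structure(list(candidates = cbind(grid, cv_fve = scores),
                 selected = sel,
                 selected_band = c(grid$f_lo[sel], grid$f_hi[sel]),
                 test_fve = rep_sel$fve, test_se = as.numeric(rep_sel$se),
                 baseline_fve = rep_base$fve,
                 baseline_se = as.numeric(rep_base$se),
                 model = models[[sel]]$model,
                 feature_cfg = models[[sel]]$cfg),
            class = "search_result")
}

#' Per-channel classifier performance profile
#'
#' Fits one single-channel classifier per good channel (evoked channel held
#' fixed at layer 4) and returns the fVE-versus-depth profile; the optimal
#' channel is the cross-validation argmax.
#'
#' @inheritParams optimize_l_band
#' @param l_band L band used for every channel's power ratio.
#' @return `search_result` with `candidates` (`channel`, `depth_um`,
#'   `cv_fve`), the selected channel, and its test fVE with jackknife SE.
#' @export
channel_profile <- function(rec, basis, scheme, Y, split, l_band = c(1, 5)) {
  good <- which(rec$channel_mask)
  if (length(good) < 2) stop("channel_profile needs at least 2 good channels")
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  scores <- numeric(length(good))
  keep <- vector("list", length(good))
  for (i in seq_along(good)) {
    cfg <- feature_config(channel_set = good[i], l_band = l_band)
    feats <- trial_features(rec, cfg)
    m <- fit_state_classifier(feats, scheme, basis, split, Y = Y)
    scores[i] <- m$cv_fve
    keep[[i]] <- list(model = m, feats = feats, cfg = cfg)
  }
  sel <- which.max(scores)
  rep_sel <- evaluate_classifier(keep[[sel]]$model, keep[[sel]]$feats, Y)
  structure(list(candidates = data.frame(channel = good,
                                         depth_um = rec$channel_depths[good],
                                         cv_fve = scores),
                 selected = sel, selected_channel = good[sel],
                 test_fve = rep_sel$fve, test_se = as.numeric(rep_sel$se),
                 model = keep[[sel]]$model, feature_cfg = keep[[sel]]$cfg),
            class = "search_result")
}

#' Channel-pair classifier search
#'
#' Pairs the optimal single channel with every other good channel: the
#' classifier input becomes three-dimensional (power ratio on the optimal
#' channel, activation on both channels). Each pair's test fVE is compared
#' against the single-channel baseline with jackknife SEs; gains above
#' 2 SE are flagged significant.
#'
#' @inheritParams optimize_l_band
#' @param optimal_channel channel from [channel_profile()].
#' @param l_band L band for the power ratio.
#' @return `search_result` with per-pair `cv_fve` and `test_fve`, the
#'   baseline single-channel test fVE, and a `significant` flag per pair.
#' @export
pair_search <- function(rec, basis, scheme, Y, split, optimal_channel,
                        l_band = c(1, 5)) {
  good <- setdiff(which(rec$channel_mask), optimal_channel)
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  base_cfg <- feature_config(channel_set = optimal_channel, l_band = l_band)
  base_feats <- trial_features(rec, base_cfg)
  base_model <- fit_state_classifier(base_feats, scheme, basis, split, Y = Y)
  rep_base <- evaluate_classifier(base_model, base_feats, Y)
  res <- data.frame(second_channel = good, cv_fve = NA_real_,
                    test_fve = NA_real_, test_se = NA_real_)
  for (i in seq_along(good)) {
    cfg <- feature_config(channel_set = c(optimal_channel, good[i]),
                          l_band = l_band)
    feats <- trial_features(rec, cfg)
    m <- fit_state_classifier(feats, scheme, basis, split, Y = Y)
    rep_i <- evaluate_classifier(m, feats, Y)
    res$cv_fve[i] <- m$cv_fve
    res$test_fve[i] <- rep_i$fve
    res$test_se[i] <- as.numeric(rep_i$se)
  }
  pool_se <- sqrt(res$test_se^2 + as.numeric(rep_base$se)^2)
  res$significant <- (res$test_fve - rep_base$fve) > 2 * pool_se
  structure(list(candidates = res, selected = which.max(res$cv_fve),
                 baseline_fve = rep_base$fve,
                 baseline_se = as.numeric(rep_base$se)),
            class = "search_result")
}

#' Side-by-side comparison of classifier input variants
#'
#' Fits classifiers from (i) the best single LFP channel, (ii) that channel
#' paired with its best partner, (iii) the spatial-PC multichannel
#' projection, and (iv) the kernel-CSD trace nearest the optimal channel,
#' and tabulates the test fVE with jackknife SE for each, including the
#' CSD-minus-LFP fVE difference.
#'
#' @inheritParams optimize_l_band
#' @param l_band L band for all variants.
#' @return data.frame with one row per variant: `variant`, `test_fve`,
#'   `test_se`, `delta_vs_single`.
#' @export
variant_comparison <- function(rec, basis, scheme, Y, split,
                               l_band = c(1, 5)) {
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  prof <- channel_profile(rec, basis, scheme, Y, split, l_band = l_band)
  best <- prof$selected_channel

  pair <- pair_search(rec, basis, scheme, Y, split, best, l_band = l_band)
  pair_best <- pair$candidates[pair$selected, ]

  spc <- compute_spatial_pc_features(rec, rec$stim_table$onset_s,
                                     feature_config(l_band = l_band))
  m_spc <- fit_state_classifier(spc$features, scheme, basis, split, Y = Y)
  rep_spc <- evaluate_classifier(m_spc, spc$features, Y)

  k <- compute_kcsd(rec, grid = rec$channel_depths[best])
  rec_csd <- rec
  rec_csd$lfp <- k$csd
  rec_csd$channel_depths <- k$depths
  rec_csd$channel_mask <- TRUE
  cfg_csd <- feature_config(channel_set = 1, l_band = l_band)
  feats_csd <- trial_features(rec_csd, cfg_csd)
  m_csd <- fit_state_classifier(feats_csd, scheme, basis, split, Y = Y)
  rep_csd <- evaluate_classifier(m_csd, feats_csd, Y)

  out <- data.frame(
    variant = c("single_best", "pair", "spatial_pc", "csd_single"),
    test_fve = c(prof$test_fve, pair_best$test_fve, rep_spc$fve,
                 rep_csd$fve),
    test_se = c(prof$test_se, pair_best$test_se, as.numeric(rep_spc$se),
                as.numeric(rep_csd$se)))
  out$delta_vs_single <- out$test_fve - out$test_fve[1]
  out
}
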