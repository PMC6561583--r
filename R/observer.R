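#' Matched-filter score trace
#'
#' `s(t) = sum_t' (x(t + t') - x(t)) xi0(t')`: the dot product of the
#' onset-subtracted 25-ms look-ahead window with the mean evoked response.
#' The score is defined only where a full look-ahead window exists; the
#' trailing samples are `NA`.
#'
#' @param x single-channel LFP trace (mV) at the template's sampling rate.
#' @param template the mean evoked response `xi0` (50 samples at 2 kHz).
#' @return List of class `score_trace`: `s` (mV^2 per sample, length of
#'   `x`), `template`, `template_norm2` (`|xi0|^2`).
#' @export
matched_filter_score <- function(x, template) {
  if (all(template == 0)) stop("template is identically zero")
  nt <- length(template)
  n <- length(x)
  # filter() computes sum_j f[j] x[t - j + 1]; reversing the template turns
  # that into the look-ahead sum a_t = sum_k template[k] x[t + k - 1]
  y <- stats::filter(x, rev(template), method = "convolution", sides = 1)
  a <- rep(NA_real_, n)
  a[seq_len(n - nt + 1)] <- y[nt:n]
  s <- a - x * sum(template)
  structure(list(s = as.numeric(s), template = template,
                 template_norm2 = sum(template^2)),
            class = "score_trace")
}

# Local maxima of `s` with prominence >= min_prom, then greedy suppression
# so surviving peaks are >= min_sep samples apart (higher peaks win).
# Thresholding this fixed set afterwards is equivalent to re-detecting at
# that threshold, because suppression only ever removes the lower peak.
# Prominence is computed in one left-to-right pass over the compressed
# peak/trough sequence with a monotonic stack (each peak's reference
# saddle is the lowest trough before a higher peak on either side).
.score_peaks <- function(s, min_prom, min_sep) {
  n <- length(s)
  x <- s
  x[is.na(x)] <- -Inf
  core <- 2:(n - 1)
  is_pk <- c(FALSE, x[core] > x[core - 1] & x[core] >= x[core + 1], FALSE)
  pk <- which(is_pk & is.finite(x))
  if (!length(pk)) return(data.frame(index = integer(0), score = numeric(0)))
  np <- length(pk)
  hp <- x[pk]
  # minimum between consecutive peaks, via grouped local minima
  trough <- numeric(max(np - 1, 0))
  if (np > 1) {
    is_mn <- c(FALSE, x[core] < x[core - 1] & x[core] <= x[core + 1], FALSE)
    mn <- which(is_mn)
    gap <- findInterval(mn, pk)
    sel <- gap >= 1 & gap < np
    trough[] <- Inf
    if (any(sel)) {
      agg <- tapply(x[mn[sel]], gap[sel], min)
      trough[as.integer(names(agg))] <- agg
    }
    missing <- which(!is.finite(trough) | trough == Inf)
    for (i in missing) trough[i] <- min(x[pk[i]:pk[i + 1]])
  }
  left_edge <- min(x[1:pk[1]])
  right_edge <- min(x[pk[np]:n])

  # the recording edges act as infinitely high boundary peaks, with the
  # edge minima as the adjacent troughs
  trough_ext <- c(left_edge, trough)
  key_l <- numeric(np)
  key_r <- rep(NA_real_, np)
  stack_idx <- integer(np + 1L); stack_min <- numeric(np + 1L)
  stack_idx[1] <- 0L; stack_min[1] <- Inf; top <- 1L
  for (i in seq_len(np)) {
    cur <- trough_ext[i]
    while (top > 1L && hp[stack_idx[top]] <= hp[i]) {
      cur <- min(cur, stack_min[top])
      key_r[stack_idx[top]] <- cur
      top <- top - 1L
    }
    key_l[i] <- min(cur, stack_min[top])
    stack_min[top] <- min(stack_min[top], cur)
    top <- top + 1L
    stack_idx[top] <- i
    stack_min[top] <- Inf
  }
  cur <- right_edge
  while (top > 1L) {
    cur <- min(cur, stack_min[top])
    key_r[stack_idx[top]] <- cur
    top <- top - 1L
  }
  prom <- hp - pmax(key_l, key_r)
  keep <- prom >= min_prom
  pk <- pk[keep]; hp <- hp[keep]
  if (!length(pk)) return(data.frame(index = integer(0), score = numeric(0)))
  # minimum-separation suppression, highest peaks first, local windows only
  alive <- rep(TRUE, length(pk))
  for (i in order(hp, decreasing = TRUE)) {
    if (!alive[i]) next
    l <- findInterval(pk[i] - min_sep, pk) + 1L
    r <- findInterval(pk[i] + min_sep - 1L, pk)
    if (r >= l) {
      rng <- l:r
      rng <- rng[rng != i & hp[rng] <= hp[i]]
      alive[rng] <- FALSE
    }
  }
  data.frame(index = pk[alive], score = hp[alive])
}

#' Detect events in a score trace
#'
#' Events are local maxima of the score exceeding the threshold of the
#' detection state at the peak time, separated from the nearest other peak
#' by at least 15 ms, with a minimum prominence of `|xi0|^2 / 2`.
#'
#' @param score a `score_trace`.
#' @param fs sampling rate, Hz.
#' @param threshold scalar threshold (state-blind) or length-3 vector of
#'   per-state thresholds.
#' @param state optional per-sample detection state in 1..3 (`NA` =
#'   unknown, never detected); required for per-state thresholds.
#' @param min_separation_s minimum peak separation (s).
#' @param min_prominence prominence floor; default `|xi0|^2 / 2`.
#' @return data.frame with `time_s`, `score`, `state` per event (possibly
#'   empty).
#' @export
detect_events <- function(score, fs, threshold, state = NULL,
                          min_separation_s = 0.015,
                          min_prominence = score$template_norm2 / 2) {
  if (length(threshold) > 1 && is.null(state))
    stop("per-state thresholds require a state trace")
  pk <- .score_peaks(score$s, min_prominence,
                     as.integer(round(min_separation_s * fs)))
  if (!nrow(pk))
    return(data.frame(time_s = numeric(0), score = numeric(0),
                      state = integer(0)))
  st <- if (is.null(state)) rep(1L, nrow(pk)) else state[pk$index]
  th <- if (length(threshold) == 1) rep(threshold, 3) else threshold
  keep <- !is.na(st) & pk$score > th[st]
  data.frame(time_s = (pk$index[keep] - 1) / fs,
             score = pk$score[keep],
             state = if (is.null(state)) rep(NA_integer_, sum(keep))
                     else st[keep])
}

#' Continuous detection-state trace
#'
#' Classifies state at every update step from sliding pre-stimulus
#' features, using the evoked component whose shape is most similar to the
#' mean response `xi0` (largest `|xi_k . xi0|`), and collapses its five
#' quintile classes to three detection states (default mapping: quintiles
#' 1-2 -> state 1, 3 -> state 2, 4-5 -> state 3). Samples before the
#' feature warm-up are marked unknown (`NA`).
#'
#' @param rec an [lfp_recording()].
#' @param model a fitted `state_classifier` (single-channel features).
#' @param channel channel the model's features were computed on.
#' @param step update step in ms.
#' @param mapping integer vector of length 5 mapping quintile class to
#'   detection state.
#' @param cfg the [feature_config()] used in fitting.
#' @return List of class `state_trace`: `state` (per-sample, 1..3 or `NA`),
#'   `occupancy` (fraction of known time per state), `pc_used`, `step_ms`,
#'   `mapping`.
#' @export
compute_state_trace <- function(rec, model, channel, step = 5,
                                mapping = c(1L, 1L, 2L, 3L, 3L),
                                cfg = feature_config(channel_set = channel)) {
  basis <- model$basis
  sims <- abs(as.numeric(t(basis$components) %*% basis$xi0))
  pc_used <- which.max(sims)
  sf <- sliding_features(rec$lfp[channel, ], rec$fs, step = step, cfg = cfg)
  x <- as.matrix(sf[, c("activation", "power_ratio")])
  colnames(x) <- model$feature_names
  lab <- .decode_posterior(model$svms[[pc_used]], x,
                           model$scheme$group_means[, pc_used])
  st_u <- mapping[lab]
  n <- ncol(rec$lfp)
  upd <- time_to_sample(sf$time_s, rec$fs)
  state <- rep(NA_integer_, n)
  reps <- diff(c(upd, n + 1L))
  state[upd[1]:n] <- rep(st_u, reps)
  occ <- tabulate(state, 3) / sum(!is.na(state))
  structure(list(state = state, occupancy = occ, pc_used = pc_used,
                 step_ms = step, mapping = mapping),
            class = "state_trace")
}

#' Hit-rate and false-alarm-rate curves per detection state
#'
#' From one pass of prominence-filtered, separation-suppressed peaks:
#' peaks inside the hit window around an onset are candidate hits for that
#' stimulus (at most one per stimulus - its largest); peaks during
#' spontaneous time (outside `exclude_s` of any onset) are candidate false
#' alarms. The hit window opens 5 ms before onset because the look-ahead
#' matched filter localizes the response to within a couple of samples,
#' which can precede the nominal onset when the response latency jitters. For any threshold, a stimulus is hit
#' when its best window peak exceeds the threshold of its pre-stimulus
#' state, and FA rates count suprathreshold spontaneous peaks per second of
#' spontaneous time in each state, so occupancy-weighted per-state FA rates
#' recombine exactly into the overall rate.
#'
#' @param score a `score_trace`.
#' @param rec the [lfp_recording()] (supplies `fs` and the stimulus table).
#' @param state_trace a `state_trace` (or `NULL` for a single-state,
#'   state-blind analysis).
#' @param hit_window length-2 window (s relative to onset) within which an
#'   event peak counts as a hit.
#' @param exclude_s peri-stimulus half-width excluded from spontaneous
#'   time.
#' @param thresholds optional explicit threshold grid; defaults to 50
#'   values spanning the observed event-score range (log-spaced when
#'   positive).
#' @param stim_subset optional indices of stimuli to include (e.g. an
#'   optimization or evaluation subset); spontaneous time is unaffected.
#' @param peaks optional precomputed peak table from an earlier
#'   `rate_curves` call on the same score trace (`attr(x, "peaks")`),
#'   avoiding a repeated peak search.
#' @return List of class `rate_curves` with the threshold grid, per-state
#'   and overall `hit` and `fa` step curves, per-stimulus best window
#'   scores and pre-stimulus states, spontaneous peak scores and states,
#'   and per-state spontaneous time `T_s`.
#' @export
rate_curves <- function(score, rec, state_trace = NULL,
                        hit_window = c(-0.005, 0.05),
                        exclude_s = 0.2, thresholds = NULL,
                        stim_subset = NULL, peaks = NULL) {
  if (length(hit_window) == 1) hit_window <- c(0, hit_window)
  fs <- rec$fs
  n <- length(score$s)
  onsets <- rec$stim_table$onset_s
  pk <- if (is.null(peaks))
    .score_peaks(score$s, score$template_norm2 / 2,
                 as.integer(round(0.015 * fs)))
  else peaks
  pk_t <- (pk$index - 1) / fs
  st <- if (is.null(state_trace)) rep(1L, n) else state_trace$state
  n_states <- if (is.null(state_trace)) 1L else 3L

  # per-stimulus best window peak and pre-stimulus state
  which_stim <- findInterval(pk_t, onsets + hit_window[1])
  in_window <- which_stim >= 1 &
    pk_t < onsets[pmax(which_stim, 1)] + hit_window[2]
  m <- rep(-Inf, length(onsets))
  best <- tapply(pk$score[in_window], which_stim[in_window], max)
  m[as.integer(names(best))] <- best
  pre_idx <- pmax(time_to_sample(onsets, fs) - 1L, 1L)
  stim_state <- st[pre_idx]

  # spontaneous peaks and spontaneous time, excluding peri-stimulus zones
  spont_mask <- rep(TRUE, n)
  for (on in onsets) {
    lo <- max(1L, time_to_sample(on - exclude_s, fs))
    hi <- min(n, time_to_sample(on + exclude_s, fs))
    spont_mask[lo:hi] <- FALSE
  }
  spont_mask[is.na(score$s) | is.na(st)] <- FALSE
  sp <- spont_mask[pk$index]
  sp_scores <- pk$score[sp]
  sp_states <- st[pk$index[sp]]
  T_s <- vapply(seq_len(n_states),
                function(s) sum(spont_mask & st == s, na.rm = TRUE) / fs,
                numeric(1))

  if (!is.null(stim_subset)) {
    m <- m[stim_subset]
    stim_state <- stim_state[stim_subset]
  }
  known <- !is.na(stim_state)
  m <- m[known]; stim_state <- stim_state[known]

  if (is.null(thresholds)) {
    rng <- range(c(sp_scores, m[is.finite(m)]))
    thresholds <- if (rng[1] > 0)
      exp(seq(log(rng[1]), log(rng[2]), length.out = 50))
    else seq(rng[1], rng[2], length.out = 50)
  }
  hit <- matrix(0, length(thresholds), n_states)
  fa <- matrix(0, length(thresholds), n_states)
  for (s in seq_len(n_states)) {
    ms <- m[stim_state == s]
    ss <- sp_scores[sp_states == s]
    hit[, s] <- vapply(thresholds, function(th) mean(ms > th), numeric(1))
    fa[, s] <- vapply(thresholds, function(th) sum(ss > th), numeric(1)) /
      T_s[s]
  }
  hit_all <- vapply(thresholds, function(th) mean(m > th), numeric(1))
  fa_all <- vapply(thresholds, function(th) sum(sp_scores > th),
                   numeric(1)) / sum(T_s)
  structure(list(thresholds = thresholds, hit = hit, fa = fa,
                 hit_overall = hit_all, fa_overall = fa_all,
                 stim_scores = m, stim_states = stim_state,
                 spont_scores = sp_scores, spont_states = sp_states,
                 T_s = T_s, n_states = n_states),
            class = "rate_curves", peaks = pk)
}

#' State-blind operating point
#'
#' Chooses the single threshold at which the state-blind hit rate falls in
#' the target range (default 80-90%): the largest such threshold, i.e. the
#' smallest false-alarm rate at which that detection level is achieved.
#' The overall false-alarm rate there becomes the budget for the
#' state-aware observer.
#'
#' @param curves a `rate_curves` object (full or optimization subset).
#' @param target hit-rate range.
#' @return List with `theta_blind`, `hit`, `fa_target`, and `attained`
#'   (`FALSE` when no threshold reaches the range and the nearest one was
#'   used).
#' @export
choose_operating_point <- function(curves, target = c(0.80, 0.90)) {
  m <- sort(unique(curves$stim_scores[is.finite(curves$stim_scores)]))
  if (!length(m)) {
    th <- max(curves$spont_scores, 0) + 1
    return(list(theta_blind = th, hit = 0,
                fa_target = sum(curves$spont_scores > th) / sum(curves$T_s),
                attained = FALSE))
  }
  # for each attainable hit level, the FA-minimal threshold sits just
  # below the next stimulus score
  cand <- m - (abs(m) * 1e-9 + 1e-12)
  hits <- vapply(cand, function(th) mean(curves$stim_scores > th),
                 numeric(1))
  inside <- hits >= target[1] & hits <= target[2]
  attained <- any(inside)
  dist <- pmin(abs(hits - target[1]), abs(hits - target[2]))
  idx <- if (attained) which(inside) else which(dist == min(dist))
  pick <- max(idx)   # largest threshold = lowest FA at that detection level
  th <- cand[pick]
  fa <- sum(curves$spont_scores > th) / sum(curves$T_s)
  list(theta_blind = th, hit = hits[pick], fa_target = fa,
       attained = attained)
}

# FA-count inversion: the smallest threshold keeping at most `count` of
# the (sorted descending) spontaneous scores above it, so that the hit
# rate at the solved threshold is maximal for that false-alarm count.
.threshold_for_count <- function(sorted_desc, count) {
  n <- length(sorted_desc)
  if (n == 0) return(-Inf)
  count <- max(0, min(count, n))
  if (count >= n) return(min(sorted_desc) - 1e-9 - abs(min(sorted_desc)) * 1e-9)
  sorted_desc[count + 1]
}

#' Constrained optimization of state-aware thresholds
#'
#' Thresholds for states 1 and 3 are varied over a grid; for each pair the
#' state-2 threshold is solved (by inverting its monotone FA step curve) so
#' that the occupancy-weighted overall false-alarm rate equals `fa_target`
#' within tolerance. Infeasible cells are marked. The optimum maximizes the
#' overall hit rate on the optimization stimuli; the chosen thresholds are
#' then applied to the reserved evaluation stimuli.
#'
#' @param curves `rate_curves` computed on the optimization stimuli.
#' @param fa_target overall false-alarm budget (events/s).
#' @param eval_curves optional `rate_curves` on reserved stimuli; per-state
#'   and overall hit rates at the chosen thresholds are reported for it.
#' @param n_grid grid resolution per axis (default 50).
#' @param theta_blind optional state-blind threshold, guaranteed to be
#'   included in the grid so the equal-threshold solution is always
#'   attainable.
#' @param tol relative FA tolerance (default 1%).
#' @return List of class `detection_report`: `thresholds` (length 3),
#'   `hit_overall`, `hit_by_state`, `fa_overall`, `fa_by_state`,
#'   `cross_state_range`, `occupancy` (spontaneous-time fractions),
#'   `eval` (same rates on the reserved stimuli, if given), `grid`
#'   (data.frame of all cells with feasibility and hit rate).
#' @export
optimize_state_thresholds <- function(curves, fa_target, eval_curves = NULL,
                                      n_grid = 50, theta_blind = NULL,
                                      tol = 0.01) {
  if (curves$n_states != 3)
    stop("optimize_state_thresholds needs 3-state curves")
  sp <- lapply(1:3, function(s)
    sort(curves$spont_scores[curves$spont_states == s], decreasing = TRUE))
  T_s <- curves$T_s
  target_count <- fa_target * sum(T_s)

  # candidate thresholds sit just below observed score steps, so every
  # grid cell aligns with an actual change in the counting functions
  pool <- c(curves$spont_scores,
            curves$stim_scores[is.finite(curves$stim_scores)])
  grid_vals <- unique(stats::quantile(pool,
                                      probs = seq(0, 1,
                                                  length.out = n_grid),
                                      type = 1, names = FALSE))
  grid_vals <- grid_vals - (abs(grid_vals) * 1e-9 + 1e-12)
  grid_vals <- c(grid_vals, max(pool) + 1)   # "detect nothing" endpoint
  if (!is.null(theta_blind)) grid_vals <- sort(c(grid_vals, theta_blind))

  cells <- expand.grid(theta1 = grid_vals, theta3 = grid_vals)
  cells$theta2 <- NA_real_
  cells$fa <- NA_real_
  cells$hit <- NA_real_
  cells$feasible <- FALSE
  hit_at <- function(th) {
    mean(curves$stim_scores > th[curves$stim_states])
  }
  for (i in seq_len(nrow(cells))) {
    c1 <- sum(sp[[1]] > cells$theta1[i])
    c3 <- sum(sp[[3]] > cells$theta3[i])
    req2 <- target_count - c1 - c3
    if (req2 < -tol * max(target_count, 1)) next
    k2 <- round(req2)
    th2 <- .threshold_for_count(sp[[2]], k2)
    achieved <- (c1 + sum(sp[[2]] > th2) + c3) / sum(T_s)
    if (abs(achieved - fa_target) > tol * max(fa_target, 1e-12) +
        1.5 / sum(T_s)) next
    cells$theta2[i] <- th2
    cells$fa[i] <- achieved
    cells$hit[i] <- hit_at(c(cells$theta1[i], th2, cells$theta3[i]))
    cells$feasible[i] <- TRUE
  }
  if (!any(cells$feasible))
    stop("no feasible (theta1, theta3) cell attains the FA target; ",
         "inspect the returned grid via rate_curves/fa curves")
  best <- which(cells$feasible)[which.max(cells$hit[cells$feasible])]
  th <- c(cells$theta1[best], cells$theta2[best], cells$theta3[best])
  report <- .detection_rates(curves, th)
  report$grid <- cells
  report$fa_target <- fa_target
  if (!is.null(eval_curves)) report$eval <- .detection_rates(eval_curves, th)
  class(report) <- "detection_report"
  report
}

# Hit/FA accounting at fixed per-state thresholds.
.detection_rates <- function(curves, th) {
  ns <- curves$n_states
  th <- rep_len(th, ns)
  hit_by_state <- vapply(seq_len(ns), function(s)
    mean(curves$stim_scores[curves$stim_states == s] > th[s]), numeric(1))
  fa_counts <- vapply(seq_len(ns), function(s)
    sum(curves$spont_scores[curves$spont_states == s] > th[s]), numeric(1))
  # a state with no spontaneous time has an undefined rate (flagged NaN),
  # but the overall rate is still well-defined from the pooled counts
  fa_by_state <- fa_counts / curves$T_s
  list(thresholds = th,
       hit_overall = mean(curves$stim_scores > th[curves$stim_states]),
       hit_by_state = hit_by_state,
       fa_overall = sum(fa_counts) / sum(curves$T_s),
       fa_by_state = fa_by_state,
       cross_state_range = diff(range(hit_by_state[is.finite(hit_by_state)])),
       occupancy = curves$T_s / sum(curves$T_s),
       n_stim_by_state = vapply(seq_len(ns), function(s)
         sum(curves$stim_states == s), numeric(1)))
}

#' State-blind detection report at a fixed threshold
#'
#' Applies one threshold in every state and parses hits and false alarms by
#' the pre-stimulus state, for comparison against the state-aware observer.
#'
#' @param curves a 3-state `rate_curves`.
#' @param theta_blind the threshold.
#' @param eval_curves optional reserved-trial curves.
#' @return A `detection_report`.
#' @export
state_blind_report <- function(curves, theta_blind, eval_curves = NULL) {
  report <- .detection_rates(curves, rep(theta_blind, curves$n_states))
  report$fa_target <- report$fa_overall
  if (!is.null(eval_curves))
    report$eval <- .detection_rates(eval_curves,
                                    rep(theta_blind, curves$n_states))
  class(report) <- "detection_report"
  report
}

#' Compare state-blind and state-aware observers
#'
#' @param report_blind `detection_report` from [state_blind_report()].
#' @param report_aware `detection_report` from
#'   [optimize_state_thresholds()].
#' @param use_eval compare on the reserved evaluation rates when both
#'   reports carry them.
#' @return List with `delta_hit` (aware minus blind overall),
#'   `hit_by_state` (2 x 3), `range_blind`, `range_aware`, `delta_range`,
#'   `occupancy`.
#' @export
evaluate_observers <- function(report_blind, report_aware,
                               use_eval = TRUE) {
  if (abs(report_blind$fa_target - report_aware$fa_target) >
      0.05 * max(report_blind$fa_target, 1e-12))
    stop("observers were set at different false-alarm targets")
  pick <- function(r) {
    if (use_eval && !is.null(r$eval)) r$eval else r
  }
  b <- pick(report_blind); a <- pick(report_aware)
  hb <- rbind(blind = b$hit_by_state, aware = a$hit_by_state)
  rng <- function(h) diff(range(h[is.finite(h)]))
  list(delta_hit = a$hit_overall - b$hit_overall,
       hit_overall = c(blind = b$hit_overall, aware = a$hit_overall),
       hit_by_state = hb,
       range_blind = rng(b$hit_by_state),
       range_aware = rng(a$hit_by_state),
       delta_range = rng(a$hit_by_state) - rng(b$hit_by_state),
       occupancy = report_aware$occupancy)
}

#' Labeled event table for a detection run
#'
#' Applies per-state thresholds to the qualifying score peaks and labels
#' every event: `hit` (the best window peak of a detected stimulus),
#' `fa` (suprathreshold spontaneous peak), plus one `miss` row per
#' undetected stimulus. Suitable for CSV export.
#'
#' @param curves a `rate_curves` object.
#' @param thresholds scalar or length-3 per-state thresholds.
#' @return data.frame with `kind` (`stimulus`/`spontaneous`), `score`,
#'   `state`, `label` in `{hit, miss, fa}`. Stimulus rows keep the
#'   stimulus order of the subset the curves were built from.
#' @export
detection_event_table <- function(curves, thresholds) {
  th <- rep_len(thresholds, curves$n_states)
  stim_lab <- ifelse(curves$stim_scores > th[curves$stim_states],
                     "hit", "miss")
  fa_keep <- curves$spont_scores > th[curves$spont_states]
  rbind(
    data.frame(kind = "stimulus", score = curves$stim_scores,
               state = curves$stim_states, label = stim_lab),
    data.frame(kind = "spontaneous",
               score = curves$spont_scores[fa_keep],
               state = curves$spont_states[fa_keep],
               label = "fa"))
}
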