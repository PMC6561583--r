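fs <- 2000
xi0 <- evoked_template((0:49) / 2, 1, 1)

# plant a triangular peak of height h at sample i (prominence h)
plant <- function(s, i, h) {
  s[(i - 2):(i + 2)] <- c(0, h / 2, h, h / 2, 0)
  s
}

test_that("the matched-filter score is exact on embedded templates", {
  x <- numeric(4000)
  x[1001:1050] <- x[1001:1050] + xi0
  sc <- matched_filter_score(x, xi0)
  expect_equal(sc$s[1001], sum(xi0^2), tolerance = 1e-12)
  expect_equal(sc$template_norm2, sum(xi0^2))
  # constant input scores exactly zero (onset subtraction)
  sc_c <- matched_filter_score(rep(3.2, 2000), xi0)
  expect_equal(max(abs(sc_c$s), na.rm = TRUE), 0, tolerance = 1e-10)
  # the trailing look-ahead region is NA
  expect_true(all(is.na(sc_c$s[(2000 - 48):2000])))
  expect_error(matched_filter_score(x, rep(0, 50)), "identically zero")
})

test_that("the score equals the brute-force lagged sum on white noise", {
  set.seed(14)
  x <- rnorm(800)
  sc <- matched_filter_score(x, xi0)
  brute <- function(t) sum((x[t + 0:49] - x[t]) * xi0)
  for (t in c(1, 57, 300, 751))
    expect_equal(sc$s[t], brute(t), tolerance = 1e-10)
})

test_that("event detection applies threshold, separation, and prominence rules", {
  s <- numeric(4000)
  s <- plant(s, 500, 6)
  sc <- toy_score(s, template_norm2 = 8)   # prominence floor 4
  expect_identical(nrow(detect_events(sc, fs, threshold = 7)), 0L)
  ev <- detect_events(sc, fs, threshold = 3)
  expect_equal(ev$time_s, (500 - 1) / fs)
  # prominence floor: a 6-peak whose saddle toward a higher 8-peak sits at
  # 3 has prominence 3 (< 4, rejected); the 8-peak itself is kept
  s2 <- rep(0, 4000)
  s2[998:1002] <- c(3, 5, 8, 5, 3)
  s2[1003:1300] <- 3
  s2[1199:1201] <- c(4, 6, 4)
  ev2 <- detect_events(toy_score(s2, 8), fs, threshold = 1)
  expect_equal(ev2$time_s, (1000 - 1) / fs)
  expect_equal(ev2$score, 8)
  # separation: peaks 10 ms apart merge into the taller one, 20 ms stay
  s3 <- plant(plant(numeric(4000), 1000, 6), 1020, 5)
  ev3 <- detect_events(toy_score(s3, 8), fs, threshold = 1)
  expect_equal(ev3$score, 6)
  s4 <- plant(plant(numeric(4000), 1000, 6), 1040, 5)
  ev4 <- detect_events(toy_score(s4, 8), fs, threshold = 1)
  expect_equal(sort(ev4$score), c(5, 6))
  # per-state thresholds require a state trace and respect it
  expect_error(detect_events(sc, fs, threshold = c(1, 2, 3)), "state trace")
  st <- rep(1L, 4000); st[1:1500] <- 3L
  ev5 <- detect_events(toy_score(s4, 8), fs, threshold = c(1, 99, 5.5),
                       state = st)
  expect_equal(ev5$score, 6)   # state-3 threshold 5.5 rejects the 5
})

test_that("rate curves match manual counts on a constructed scene", {
  n <- 20 * fs
  s <- numeric(n)
  # stimulus at 5 s (window peak height 10), stimulus at 12 s (no peak)
  s <- plant(s, 5.01 * fs + 1, 10)
  # spontaneous peaks: 2 s (h 6, state 1), 8 s (h 5, state 2),
  # 15 s (h 4.5, state 3), 16 s (h 7, state 3)
  s <- plant(s, 2 * fs + 1, 6)
  s <- plant(s, 8 * fs + 1, 5)
  s <- plant(s, 15 * fs + 1, 4.5)
  s <- plant(s, 16 * fs + 1, 7)
  s[(n - 48):n] <- NA
  state <- c(rep(1L, 6 * fs), rep(2L, 4 * fs), rep(3L, 10 * fs))
  stt <- structure(list(state = state), class = "state_trace")
  rec <- toy_recording(n_ch = 1, dur = 20, onsets = c(5, 12),
                       trace_fun = function(ch, t) rep(0, length(t)))
  cv <- rate_curves(toy_score(s, 8), rec, stt, thresholds = c(3, 5.5))
  # spontaneous time per state: exclusion of [4.8,5.2] (state 1) and
  # [11.8,12.2] (state 3); NA tail also leaves state 3
  expect_equal(cv$T_s[1], 5.6, tolerance = 1e-3)
  expect_equal(cv$T_s[2], 4.0, tolerance = 1e-3)
  expect_equal(cv$T_s[3], 10 - 0.4 - 49 / fs, tolerance = 1e-3)
  # theta = 3: all four spontaneous peaks count; stimulus 1 hit, 2 missed
  expect_equal(cv$fa[1, ], c(1 / cv$T_s[1], 1 / cv$T_s[2], 2 / cv$T_s[3]))
  expect_equal(cv$hit[1, ], c(1, NaN, 0))
  expect_equal(cv$hit_overall[1], 0.5)
  # theta = 5.5: only the 6 (state 1) and 7 (state 3) survive
  expect_equal(cv$fa[2, ], c(1 / cv$T_s[1], 0, 1 / cv$T_s[3]))
  # occupancy-weighted per-state FA recombines exactly to the overall rate
  for (i in 1:2)
    expect_equal(sum(cv$fa[i, ] * cv$T_s) / sum(cv$T_s), cv$fa_overall[i],
                 tolerance = 1e-12)
})

test_that("rate curves are monotone non-increasing in the threshold", {
  fx <- fx_pipeline()
  sc <- matched_filter_score(fx$rec$lfp[fx$layer_map$l4_center, ],
                             fx$basis$xi0)
  stt <- compute_state_trace(fx$rec, fx$model, fx$layer_map$l4_center,
                             step = 25, cfg = fx$cfg)
  cv <- rate_curves(sc, fx$rec, stt)
  expect_true(all(diff(cv$hit_overall) <= 1e-12))
  expect_true(all(diff(cv$fa_overall) <= 1e-12))
  for (s in 1:3) {
    expect_true(all(diff(cv$fa[, s]) <= 1e-12))
    hs <- cv$hit[, s]
    expect_true(all(diff(hs[is.finite(hs)]) <= 1e-12))
  }
  for (i in seq_along(cv$thresholds))
    expect_equal(sum(cv$fa[i, ] * cv$T_s) / sum(cv$T_s), cv$fa_overall[i],
                 tolerance = 1e-12)
})

test_that("state traces are piecewise constant with known warm-up and occupancy", {
  fx <- fx_pipeline()
  stt <- compute_state_trace(fx$rec, fx$model, fx$layer_map$l4_center,
                             step = 25, cfg = fx$cfg)
  expect_true(all(is.na(stt$state[1:(2 * fs - 1)])))
  known <- stt$state[!is.na(stt$state)]
  expect_true(all(known %in% 1:3))
  expect_equal(sum(stt$occupancy), 1, tolerance = 1e-12)
  # changes only at update boundaries (multiples of the step)
  chg <- which(diff(stt$state) != 0)
  step_samples <- 25 / 1000 * fs
  expect_true(all((chg - 2 * fs) %% step_samples == 0))
  # a constant input yields a constant state
  rec_c <- toy_recording(n_ch = 8, dur = 8,
                         trace_fun = function(ch, t) rep(0, length(t)))
  stt_c <- compute_state_trace(rec_c, fx$model, fx$layer_map$l4_center,
                               step = 50, cfg = fx$cfg)
  expect_length(unique(stt_c$state[!is.na(stt_c$state)]), 1L)
})

test_that("the operating point attains 80-90% detection at the lowest FA", {
  set.seed(6)
  m <- c(runif(80, 5, 10), runif(20, 0.5, 2))   # 80% strong, 20% weak
  curves <- structure(list(
    stim_scores = m, stim_states = rep(1L, 100),
    spont_scores = runif(200, 0, 6), spont_states = rep(1L, 200),
    T_s = 100, n_states = 1L), class = "rate_curves")
  op <- choose_operating_point(curves)
  expect_true(op$attained)
  hit_at <- mean(m > op$theta_blind)
  expect_gte(hit_at, 0.80)
  expect_lte(hit_at, 0.90)
  # no lower-FA threshold keeps the hit rate in range
  expect_lt(mean(m > op$theta_blind + 0.2), 0.80)
  expect_equal(op$fa_target,
               sum(curves$spont_scores > op$theta_blind) / 100)
  # unattainable range is flagged and the nearest hit rate returned
  curves2 <- curves; curves2$stim_scores <- rep(-Inf, 100)
  op2 <- choose_operating_point(curves2)
  expect_false(op2$attained)
})

test_that("constrained threshold optimization matches an exhaustive oracle", {
  set.seed(21)
  mk_curves <- function(shift) {
    stim_states <- rep(1:3, each = 15)
    m <- round(2 * c(rnorm(15, 5 + shift[1], 2), rnorm(15, 5 + shift[2], 2),
                     rnorm(15, 5 + shift[3], 2))) / 2
    spont <- round(2 * abs(c(rnorm(20, 2, 1.2), rnorm(20, 2, 1.2),
                             rnorm(20, 2, 1.2)))) / 2
    structure(list(stim_scores = m, stim_states = stim_states,
                   spont_scores = spont,
                   spont_states = rep(1:3, each = 20),
                   T_s = c(50, 50, 50), n_states = 3L),
              class = "rate_curves")
  }
  curves <- mk_curves(c(-2.5, 0, 2.5))
  fa_target <- 0.1
  tol_abs <- 0.01 * fa_target + 1.5 / 150
  rep_aw <- optimize_state_thresholds(curves, fa_target, n_grid = 100)
  expect_lte(abs(rep_aw$fa_overall - fa_target), tol_abs + 1e-12)
  # exhaustive brute force over every score step for the outer thresholds,
  # with the state-2 threshold solved for the FA budget as the method
  # prescribes (independent re-derivation with explicit loops)
  cand <- sort(unique(c(curves$spont_scores, curves$stim_scores))) - 1e-9
  sp2 <- sort(curves$spont_scores[curves$spont_states == 2],
              decreasing = TRUE)
  target_count <- fa_target * sum(curves$T_s)
  best <- -Inf
  for (t1 in cand) for (t3 in cand) {
    c1 <- sum(curves$spont_scores[curves$spont_states == 1] > t1)
    c3 <- sum(curves$spont_scores[curves$spont_states == 3] > t3)
    k2 <- round(target_count - c1 - c3)
    if (k2 < 0) next
    t2 <- if (k2 >= length(sp2)) min(sp2) - 1 else sp2[k2 + 1]
    fa <- (c1 + sum(sp2 > t2) + c3) / sum(curves$T_s)
    if (abs(fa - fa_target) > tol_abs) next
    hit <- mean(curves$stim_scores > c(t1, t2, t3)[curves$stim_states])
    best <- max(best, hit)
  }
  expect_equal(rep_aw$hit_overall, best, tolerance = 1e-9)
  # symmetric per-state distributions: no gain over the blind observer
  curves_sym <- mk_curves(c(0, 0, 0))
  op <- choose_operating_point(curves_sym)
  blind <- state_blind_report(curves_sym, op$theta_blind)
  aw <- optimize_state_thresholds(curves_sym, op$fa_target, n_grid = 25,
                                  theta_blind = op$theta_blind)
  expect_gte(aw$hit_overall + 1e-9, blind$hit_overall)
  expect_lt(aw$hit_overall - blind$hit_overall, 0.06)
  # an unreachable FA budget is an explicit error
  expect_error(optimize_state_thresholds(curves, fa_target = 50,
                                         n_grid = 10),
               "no feasible")
})

test_that("observer comparison reports deltas, ranges and occupancy", {
  mk_report <- function(hits, fa) {
    structure(list(thresholds = c(1, 1, 1), hit_overall = mean(hits),
                   hit_by_state = hits, fa_overall = fa,
                   fa_by_state = rep(fa, 3),
                   cross_state_range = diff(range(hits)),
                   occupancy = c(0.2, 0.5, 0.3), fa_target = fa),
              class = "detection_report")
  }
  blind <- mk_report(c(0.6, 0.8, 0.9), 1.6)
  aware <- mk_report(c(0.76, 0.82, 0.83), 1.6)
  cmp <- evaluate_observers(blind, aware)
  expect_equal(cmp$range_blind, 0.3)
  expect_equal(cmp$range_aware, 0.07, tolerance = 1e-9)
  expect_equal(cmp$delta_hit,
               mean(c(0.76, 0.82, 0.83)) - mean(c(0.6, 0.8, 0.9)))
  expect_error(evaluate_observers(blind, mk_report(c(0.7, 0.7, 0.7), 3.0)),
               "different false-alarm targets")
})
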