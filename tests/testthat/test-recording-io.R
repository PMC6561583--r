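make_rec <- function(n_ch = 3, n = 4000, fs = 2000, seed = 1) {
  set.seed(seed)
  lfp_recording(matrix(rnorm(n_ch * n), n_ch, n), fs = fs,
                channel_depths = (seq_len(n_ch) - 1) * 25,
                stim_table = data.frame(onset_s = c(0.5, 1.2),
                                        velocity_deg_s = c(1000, 250)),
                meta = list(animal = "synthetic-01"))
}

test_that("write then read round-trips every field losslessly", {
  rec <- make_rec()
  stem <- tempfile()
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_equal(back$lfp, rec$lfp, tolerance = 0)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channel_depths, rec$channel_depths)
  expect_identical(back$channel_mask, rec$channel_mask)
  expect_equal(back$stim_table, rec$stim_table)
  expect_identical(back$meta$animal, "synthetic-01")
})

test_that("missing container pieces raise named errors", {
  rec <- make_rec()
  stem <- tempfile()
  write_recording(rec, stem)
  file.remove(paste0(stem, ".stim.csv"))
  expect_error(read_recording(stem), "missing file.*stim")
  expect_error(read_recording(tempfile()), "missing file")
  # sidecar lacking a required dataset
  stem2 <- tempfile()
  write_recording(rec, stem2)
  side <- jsonlite::read_json(paste0(stem2, ".json"))
  side$fs <- NULL
  jsonlite::write_json(side, paste0(stem2, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(stem2), "missing dataset: fs")
  # truncated binary -> shape mismatch
  stem3 <- tempfile()
  write_recording(rec, stem3)
  bin <- paste0(stem3, ".lfp.bin")
  writeBin(readBin(bin, "raw", n = 100), bin)
  expect_error(read_recording(stem3), "shape mismatch")
})

test_that("container invariants reject bad inputs", {
  expect_error(lfp_recording(matrix(0, 3, 100), 2000,
                             channel_depths = c(0, 50, 25),
                             stim_table = data.frame(onset_s = numeric(0))),
               "monotone")
  expect_error(lfp_recording(matrix(0, 2, 100), 2000,
                             channel_depths = c(0, 25),
                             stim_table = data.frame(onset_s = 5)),
               "\\[0, duration\\)")
  # permuted depths are fine if the offending channel is masked
  rec <- lfp_recording(matrix(0, 3, 100), 2000,
                       channel_depths = c(0, 50, 25),
                       stim_table = data.frame(onset_s = numeric(0)),
                       channel_mask = c(TRUE, FALSE, TRUE))
  expect_s3_class(rec, "lfp_recording")
})

test_that("downsampling preserves slow content and sample arithmetic", {
  fs0 <- 30000
  n <- fs0 * 2
  t <- (seq_len(n) - 1) / fs0
  x <- sin(2 * pi * 10 * t)
  rec <- lfp_recording(matrix(x, 1, n), fs0, channel_depths = 0,
                       stim_table = data.frame(onset_s = 0.5))
  # identity when already at the target rate
  rec2k <- lfp_recording(matrix(sin(2 * pi * 10 * (0:3999) / 2000), 1, 4000),
                         2000, channel_depths = 0,
                         stim_table = data.frame(onset_s = 0.5))
  expect_identical(downsample_recording(rec2k, 2000), rec2k)
  down <- downsample_recording(rec, 2000)
  expect_identical(ncol(down$lfp), as.integer(floor(n * 2000 / 30000)))
  expect_identical(down$fs, 2000)
  # amplitude of a 10-Hz sinusoid preserved within 1% (away from edges)
  mid <- 1000:3000
  ref <- sin(2 * pi * 10 * (mid - 1) / 2000)
  expect_lt(max(abs(down$lfp[1, mid] - ref)), 0.01)
  expect_identical(down$stim_table$onset_s, 0.5)
  expect_error(downsample_recording(rec2k, 4000), "exceeds")
  expect_error(downsample_recording(rec, 1700), "divide")
})

test_that("line-noise regression removes mains harmonics and only them", {
  fs <- 2000
  n <- fs * 8
  t <- (seq_len(n) - 1) / fs
  clean <- 0.3 * sin(2 * pi * 4 * t)
  mains <- 0.2 * sin(2 * pi * 60 * t + 0.7) + 0.1 * sin(2 * pi * 180 * t + 2.1)
  onsets <- c(2, 5)
  rec_clean <- lfp_recording(matrix(clean, 1, n), fs, 0,
                             data.frame(onset_s = onsets))
  rec_noisy <- lfp_recording(matrix(clean + mains, 1, n), fs, 0,
                             data.frame(onset_s = onsets))
  # without mains content the trace is essentially untouched
  out_clean <- remove_line_noise(rec_clean)
  expect_lt(max(abs(out_clean$lfp - rec_clean$lfp)), 0.01)
  # with mains content, line power drops by > 20 dB over the peri-stimulus
  # window while the 5-Hz signal survives
  out <- remove_line_noise(rec_noisy)
  idx <- window_samples(onsets[1] - 0.55, onsets[1] + 0.3, fs)
  pow_at <- function(x, f) {
    p <- periodogram_psd(x, fs)
    sum(p$power[abs(p$freq - f) < 0.8])
  }
  for (f in c(60, 180)) {
    before <- pow_at(rec_noisy$lfp[1, idx], f)
    after <- pow_at(out$lfp[1, idx], f)
    expect_lt(10 * log10(after / before), -20)
  }
  expect_equal(pow_at(out$lfp[1, idx], 4), pow_at(rec_noisy$lfp[1, idx], 4),
               tolerance = 0.05)
  # the default harmonic set spans 60..300 Hz in 60-Hz steps
  expect_identical(eval(formals(remove_line_noise)$harmonics),
                   seq(60, 300, by = 60))
  expect_error(remove_line_noise(rec_noisy, fit_window = c(-0.6, -0.2)),
               "500 ms")
  expect_error(remove_line_noise(rec_noisy, fit_window = c(-0.45, 0.05)),
               "overlaps")
})

test_that("recording-wide line-noise fit subtracts a global sinusoid", {
  fs <- 2000
  n <- fs * 4
  t <- (seq_len(n) - 1) / fs
  rec <- lfp_recording(matrix(0.25 * sin(2 * pi * 60 * t + 1), 1, n), fs, 0,
                       data.frame(onset_s = numeric(0)))
  out <- remove_line_noise(rec, per_trial = FALSE)
  expect_lt(stats::sd(out$lfp[1, ]), 0.01)
})

test_that("channels with slow irregular drift are flagged", {
  fs <- 2000
  n <- fs * 70
  set.seed(4)
  base <- 0.1 * sin(2 * pi * 3 * (seq_len(n) - 1) / fs)
  lfp <- rbind(base, base, base, base)
  rec <- lfp_recording(lfp + matrix(rnorm(4 * n, sd = 1e-3), 4, n), fs,
                       channel_depths = (0:3) * 25,
                       stim_table = data.frame(onset_s = numeric(0)))
  expect_true(all(flag_bad_channels(rec)))
  # inject a large slow ramp on channel 3
  rec$lfp[3, ] <- rec$lfp[3, ] + seq(0, 5, length.out = n)
  mask <- flag_bad_channels(rec)
  expect_identical(mask, c(TRUE, TRUE, FALSE, TRUE))
  short <- lfp_recording(matrix(0, 2, fs * 10), fs, c(0, 25),
                         data.frame(onset_s = numeric(0)))
  expect_error(flag_bad_channels(short), "60 s")
})

test_that("decimation commutes with evoked-window extraction", {
  fs0 <- 30000
  dur <- 8
  t <- (seq_len(fs0 * dur) - 1) / fs0
  onsets <- c(3, 5.5)
  x <- 0.3 * sin(2 * pi * 4 * t)
  for (on in onsets) {
    idx <- window_samples(on, on + 0.06, fs0)
    x[idx] <- x[idx] + evoked_template((seq_along(idx) - 1) / fs0 * 1000,
                                       1, 1)
  }
  rec30 <- lfp_recording(matrix(x, 1, length(x)), fs0, 0,
                         data.frame(onset_s = onsets))
  ev_then_down <- extract_evoked(downsample_recording(rec30, 2000), 1)
  # direct 2-kHz sampling of the same underlying signal
  t2 <- (seq_len(2000 * dur) - 1) / 2000
  x2 <- 0.3 * sin(2 * pi * 4 * t2)
  for (on in onsets) {
    idx <- window_samples(on, on + 0.06, 2000)
    x2[idx] <- x2[idx] + evoked_template((seq_along(idx) - 1) / 2, 1, 1)
  }
  ev_direct <- extract_evoked(lfp_recording(matrix(x2, 1, length(x2)),
                                            2000, 0,
                                            data.frame(onset_s = onsets)), 1)
  # the anti-aliasing filter smooths the sharp template slightly; windows
  # agree within a few percent of the dip
  expect_lt(max(abs(ev_then_down$Y - ev_direct$Y)), 0.05)
})

test_that("labeled event tables partition detections into hit, miss and fa", {
  curves <- structure(list(
    stim_scores = c(6, 2, -Inf), stim_states = c(1L, 2L, 3L),
    spont_scores = c(5, 1), spont_states = c(1L, 3L),
    T_s = c(10, 10, 10), n_states = 3L), class = "rate_curves")
  tab <- detection_event_table(curves, thresholds = c(4, 4, 0.5))
  expect_identical(tab$label[tab$kind == "stimulus"],
                   c("hit", "miss", "miss"))
  expect_identical(nrow(tab[tab$label == "fa", ]), 2L)
  expect_identical(tab$score[tab$label == "fa"], c(5, 1))
})
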