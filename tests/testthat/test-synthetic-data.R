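test_that("unmodulated config yields perfectly regular beats", {
  cfg <- sim_config(duration_s = 60, mean_ibi_s = 1.0,
                    vlf_amp = 0, lf_amp = 0, hf_amp = 0)
  gt <- simulate_ibi(cfg)
  expect_equal(gt$ibi_s, rep(1.0, length(gt$ibi_s)), tolerance = 1e-12)
  expect_equal(length(gt$beat_times_s), 60)
  expect_equal(diff(gt$beat_times_s), gt$ibi_s)
  expect_true(all(diff(gt$beat_times_s) > 0))
  expect_identical(gt$label, "alert")
})

test_that("simulation is bit-identical under a fixed seed and varies across seeds", {
  cfg <- sim_config(duration_s = 120, noise_sd = 0.01, seed = 42)
  gt1 <- simulate_ibi(cfg)
  gt2 <- simulate_ibi(cfg)
  expect_identical(gt1$beat_times_s, gt2$beat_times_s)
  gt3 <- simulate_ibi(sim_config(duration_s = 120, noise_sd = 0.01, seed = 43))
  expect_false(identical(gt1$beat_times_s, gt3$beat_times_s))
})

test_that("LF-only modulation concentrates resampled power in the LF band", {
  cfg <- sim_config(duration_s = 125, lf_amp = 0.05, hf_amp = 0, vlf_amp = 0,
                    seed = 1)
  gt <- simulate_ibi(cfg)
  w <- cut_windows(resample_ibi(gt_knots(gt)), length_s = 120)[[1]]
  p <- hrv_psd(w)
  non_dc <- p$freq > 0.003
  in_lf <- p$freq >= 0.04 & p$freq <= 0.15
  expect_gt(sum(p$density[non_dc & in_lf]) / sum(p$density[non_dc]), 0.95)
})

test_that("amplitudes driving the IBI towards zero are rejected with a diagnostic", {
  cfg <- sim_config(duration_s = 60, mean_ibi_s = 0.5, lf_amp = 0.6)
  expect_error(simulate_ibi(cfg), "amplitudes too large")
})

test_that("drowsy nonstationary schedule ramps the mean interval upward", {
  cfg <- sim_config(duration_s = 600, nonstationary = TRUE, seed = 5)
  gt <- simulate_ibi(cfg)
  expect_identical(gt$label, "drowsy")
  n <- length(gt$ibi_s)
  expect_gt(mean(gt$ibi_s[(n - 50):n]), mean(gt$ibi_s[1:50]) + 0.05)
})

test_that("rendered pulse train places template maxima on the beat grid", {
  beats <- seq(0.5, 59.5, by = 1)   # 60 bpm
  cfg <- sim_config(duration_s = 60, mean_ibi_s = 1.0)
  rec <- render_ppg(list(beat_times_s = beats), fs_hz = 40, config = cfg)
  x <- rec$samples
  loc <- which(x > 0.9 & x >= c(-Inf, x[-length(x)]) & x > c(x[-1], Inf))
  expect_equal(length(loc), 60)
  expect_true(all(diff(loc) == 40))
  expect_equal(attr(rec, "beat_idx"), as.integer(round(beats * 40) + 1L))
})

test_that("dominant baseline wander drives the local waveform maxima", {
  cfg <- sim_config(duration_s = 60, mean_ibi_s = 1.0,
                    vlf_amp = 0, lf_amp = 0, hf_amp = 0,
                    baseline_wander_amp = 10, baseline_wander_freq_hz = 0.05)
  gt <- simulate_ibi(cfg)
  rec <- render_ppg(gt, fs_hz = 40, config = cfg)
  # block maxima over the rising quarter-period (0..5 s) increase monotonically
  block_max <- sapply(0:4, function(b) max(rec$samples[(b * 40 + 1):((b + 1) * 40)]))
  expect_true(all(diff(block_max) > 0))
})

test_that("an empty beat list renders a flat baseline record", {
  cfg <- sim_config(duration_s = 10)
  rec <- render_ppg(list(beat_times_s = numeric(0)), fs_hz = 40, config = cfg)
  expect_true(all(rec$samples == 0))
})

test_that("simulated PERCLOS respects the alert and drowsy bands", {
  a <- simulate_perclos("alert", 50, seed = 1)
  d <- simulate_perclos("drowsy", 50, seed = 1)
  expect_length(a, 50)
  expect_true(all(a >= 0 & a < 0.30))
  expect_true(all(d >= 0.30 & d <= 0.40))
  expect_identical(simulate_perclos("alert", 0), numeric(0))
  expect_identical(simulate_perclos("drowsy", 5, seed = 9),
                   simulate_perclos("drowsy", 5, seed = 9))
})

test_that("PPG CSV round-trips through write and read", {
  cfg <- sim_config(duration_s = 12, seed = 2)
  gt <- simulate_ibi(cfg)
  rec <- render_ppg(gt, fs_hz = 40, config = cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ppg_csv(rec, path, seed = 2)
  back <- read_ppg_csv(path)
  expect_equal(back$fs_hz, 40)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)
})
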