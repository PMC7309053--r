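test_that("fixed-window segmentation obeys floor arithmetic and drops remainders", {
  rec <- ecg_record(rnorm(1000), 128, "s1")
  cfg <- segmentation_config(mode = "fixed_window", window_samples = 288)
  segs <- segment_fixed(rec, cfg)
  expect_equal(nrow(segs$windows), 3L)            # floor(1000/288)
  expect_equal(ncol(segs$windows), 288L)
  expect_equal(segs$labels, rep("s1", 3))

  exact <- segment_fixed(ecg_record(rnorm(288), 128), cfg)
  expect_equal(nrow(exact$windows), 1L)
  short <- segment_fixed(ecg_record(rnorm(287), 128), cfg)
  expect_equal(nrow(short$windows), 0L)
})

test_that("fixed windows tile the record prefix exactly", {
  x <- rnorm(650)
  segs <- segment_fixed(ecg_record(x, 100),
                        segmentation_config(mode = "fixed_window",
                                            window_samples = 100))
  expect_identical(as.numeric(t(segs$windows)), x[1:600])
})

test_that("R-peak grouping trims, groups by n, and drops leftovers", {
  fs <- 360
  n <- 20000
  rec <- ecg_record(rnorm(n), fs, "p")
  cfg <- segmentation_config(group_n = 3, beat_window_samples = 444)
  peaks9 <- rpeak_list(seq(500, by = 600, length.out = 9))
  expect_equal(nrow(segment_rpeak_grouped(rec, peaks9, cfg)$windows), 3L)
  peaks10 <- rpeak_list(seq(500, by = 600, length.out = 10))
  g10 <- segment_rpeak_grouped(rec, peaks10, cfg)
  expect_equal(nrow(g10$windows), 3L)             # one beat left over
  expect_equal(ncol(g10$windows), 3L * 444L)
  # beats running off the record are discarded
  edge <- rpeak_list(c(10, seq(500, by = 600, length.out = 6), n - 10))
  g_edge <- segment_rpeak_grouped(rec, edge, cfg)
  expect_equal(nrow(g_edge$windows), 2L)          # 6 usable of 8 candidates
})

test_that("grouped windows concatenate the per-beat segments in order", {
  rec <- ecg_record(seq_len(5000), 360, "q")
  cfg <- segmentation_config(group_n = 2, beat_window_samples = 90,
                             beat_pre_frac = 1 / 3)
  peaks <- rpeak_list(c(1000, 2000))
  g <- segment_rpeak_grouped(rec, peaks, cfg)
  pre <- round(90 / 3)
  expect_equal(as.numeric(g$windows[1, 1:90]), (1000 - pre):(1000 + 60 - 1))
  expect_equal(as.numeric(g$windows[1, 91:180]), (2000 - pre):(2000 + 60 - 1))
})

test_that("detector returns nothing on flat or too-short records", {
  expect_length(detect_rpeaks(ecg_record(rep(0, 5000), 360)), 0L)
  expect_length(detect_rpeaks(ecg_record(rnorm(30), 360)), 0L)
})

test_that("detector recovers all beats of a clean 60 bpm record at the right spacing", {
  cfg <- synth_config(duration_s = 10, sampling_rate_hz = 360, noise_sd = 0,
                      baseline_wander_amp = 0, seed = 4)
  out <- generate_record(sample_subject(4, 1, mean_hr_bpm = 60, hr_sd_bpm = 0),
                         cfg)
  expect_length(out$r_peaks, 10L)
  expect_true(all(diff(out$r_peaks) == 360L))
  peaks <- detect_rpeaks(preprocess_record(out$record))
  expect_length(peaks, 10L)
  expect_true(all(abs(as.integer(peaks) - out$r_peaks) <= 0.05 * 360))
  expect_equal(mean(diff(as.integer(peaks))), 360, tolerance = 0.01)
})

test_that("detector precision and recall reach 0.99 at 10 dB SNR", {
  for (fs in c(128, 360)) {
    base <- synth_config(num_subjects = 3, duration_s = 30,
                         sampling_rate_hz = fs, seed = 31)
    nsd <- noise_sd_for_snr(sample_subject(31, 1), base, 10)
    coh <- generate_cohort(synth_config(num_subjects = 3, duration_s = 30,
                                        sampling_rate_hz = fs, noise_sd = nsd,
                                        seed = 31))
    for (i in seq_along(coh$records)) {
      pk <- detect_rpeaks(preprocess_record(coh$records[[i]]))
      st <- rpeak_match_stats(pk, coh$r_peaks[[i]], fs, tol_s = 0.05)
      expect_gte(st$precision, 0.99)
      expect_gte(st$recall, 0.99)
    }
  }
})

test_that("detected peaks always respect the refractory bound", {
  set.seed(9)
  cfgs <- list(
    ecg_record(rnorm(7200), 360),                                  # pure noise
    preprocess_record(generate_record(sample_subject(5, 2),
      synth_config(duration_s = 20, noise_sd = 0.3, seed = 5))$record),
    preprocess_record(generate_record(sample_subject(6, 1,
      mean_hr_bpm = 180, hr_sd_bpm = 30),
      synth_config(duration_s = 20, noise_sd = 0.05, seed = 6))$record))
  for (rec in cfgs) {
    pk <- detect_rpeaks(rec)
    if (length(pk) > 1L)
      expect_true(all(diff(as.integer(pk)) >= 0.2 * rec$sampling_rate_hz))
  }
})

test_that("refractory rule keeps the larger-amplitude member of a close pair", {
  # candidates 50 ms apart at 360 Hz (18 samples << 72-sample refractory)
  keep <- ecgid:::enforce_refractory(c(1000L, 1018L), amp = c(0.4, 0.9),
                                     refr = 72L)
  expect_identical(keep, 1018L)
  keep2 <- ecgid:::enforce_refractory(c(1000L, 1018L), amp = c(0.9, 0.4),
                                      refr = 72L)
  expect_identical(keep2, 1000L)
  # a distant third candidate survives untouched
  keep3 <- ecgid:::enforce_refractory(c(1000L, 1018L, 2000L),
                                      amp = c(0.4, 0.9, 0.5), refr = 72L)
  expect_identical(keep3, c(1018L, 2000L))
})

test_that("segment sets are homogeneous and label-consistent across modes", {
  coh <- generate_cohort(synth_config(num_subjects = 2, duration_s = 20,
                                      sampling_rate_hz = 128, noise_sd = 0.03,
                                      seed = 12))
  for (cfg in list(segmentation_config(mode = "fixed_window", window_samples = 288),
                   segmentation_config(beat_window_samples = 128, group_n = 3))) {
    segs <- do.call(bind_segments, lapply(coh$records, function(r)
      segment_record(preprocess_record(r), cfg)))
    expect_gt(nrow(segs$windows), 0L)
    expect_length(segs$labels, nrow(segs$windows))
    expect_setequal(unique(segs$labels), c("S01", "S02"))
  }
})

test_that("window sizing converts to the expected durations", {
  expect_equal(segment_duration_s(288, 128), 2.25)
  expect_equal(round(segment_duration_s(444, 360), 2), 1.23)
})

test_that("ungrouping windows inverts the concatenation step", {
  s <- segment_set(matrix(1:12, 2, 6), c("a", "b"), 100, "rpeak_grouped")
  b <- split_group_windows(s, 3)
  expect_equal(nrow(b$windows), 6L)
  expect_equal(ncol(b$windows), 2L)
  expect_identical(b$labels, c("a", "a", "a", "b", "b", "b"))
  # window row 1 = (1,3,5,7,9,11): beats (1,3), (5,7), (9,11) in order
  expect_equal(b$windows[1, ], c(1, 3))
  expect_equal(b$windows[2, ], c(5, 7))
  expect_equal(b$windows[3, ], c(9, 11))
  # re-concatenating the beat rows reproduces the group windows
  rebuilt <- cbind(b$windows[c(TRUE, FALSE, FALSE), ],
                   b$windows[c(FALSE, TRUE, FALSE), ],
                   b$windows[c(FALSE, FALSE, TRUE), ])
  expect_equal(rebuilt, s$windows)
  expect_error(split_group_windows(s, 4), "multiple of group_n")
})
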