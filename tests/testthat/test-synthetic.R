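test_that("subject morphologies are deterministic, distinct, and well-ordered", {
  m1 <- sample_subject(42, 3)
  m2 <- sample_subject(42, 3)
  expect_identical(m1, m2)
  m3 <- sample_subject(42, 4)
  expect_false(identical(m1$waves, m3$waves))

  for (i in 1:100) {
    m <- sample_subject(7, i)
    th <- m$waves[, "theta"]
    expect_true(all(diff(th[c("P", "Q", "R", "S", "T")]) > 0))
    expect_equal(unname(which.max(abs(m$waves[, "amplitude"]))),
                 which(rownames(m$waves) == "R"))
    expect_true(m$mean_hr_bpm > 0)
  }
})

test_that("clean fixed-rate record lays beats at exact RR spacing", {
  cfg <- synth_config(duration_s = 10, sampling_rate_hz = 360, noise_sd = 0,
                      baseline_wander_amp = 0, seed = 1)
  out <- generate_record(sample_subject(1, 1, mean_hr_bpm = 60, hr_sd_bpm = 0),
                         cfg)
  expect_length(out$r_peaks, 10L)
  expect_true(all(diff(out$r_peaks) == 360L))
})

test_that("ground-truth R positions sit on local maxima of the clean signal", {
  cfg <- synth_config(duration_s = 20, sampling_rate_hz = 360, noise_sd = 0,
                      baseline_wander_amp = 0, seed = 13)
  for (i in 1:3) {
    out <- generate_record(sample_subject(13, i), cfg)
    x <- out$record$samples
    for (p in out$r_peaks) {
      window <- x[max(1, p - 2):min(length(x), p + 2)]
      expect_lte(abs(which.max(window) - 3), 1)  # maximum within +-1 sample
    }
  }
})

test_that("RR intervals never violate the 200 ms clinical floor", {
  set.seed(3)
  rr <- ecgid:::sample_rr_intervals(1e4, mean_hr_bpm = 240, hr_sd_bpm = 80)
  expect_true(all(rr >= 0.2))
  rr2 <- ecgid:::sample_rr_intervals(1e4, mean_hr_bpm = 70, hr_sd_bpm = 2)
  expect_true(all(rr2 >= 0.2))
  expect_equal(mean(rr2), 60 / 70, tolerance = 0.01)
})

test_that("records and cohorts regenerate bit-identically under a seed", {
  cfg <- synth_config(num_subjects = 2, duration_s = 10, noise_sd = 0.05,
                      seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records[[1]]$samples, b$records[[1]]$samples)
  expect_identical(a$records[[2]]$samples, b$records[[2]]$samples)
  expect_identical(a$r_peaks, b$r_peaks)
  expect_equal(vapply(a$records, `[[`, character(1), "subject_id"),
               c("S01", "S02"))
})

test_that("cohort scales to the reference database sizes", {
  coh <- generate_cohort(synth_config(num_subjects = 18, duration_s = 5,
                                      sampling_rate_hz = 128, seed = 2))
  expect_length(coh$records, 18L)
  expect_true(all(vapply(coh$records, function(r)
    r$sampling_rate_hz == 128, logical(1))))
})

test_that("degenerate durations are rejected", {
  cfg <- synth_config(duration_s = 0.5, seed = 1)
  expect_error(generate_record(sample_subject(1, 1, mean_hr_bpm = 60), cfg),
               "duration")
})

test_that("rising noise monotonically degrades detector recovery", {
  sds <- c(0, 0.05, 0.15, 0.3, 0.6)
  f1s <- vapply(sds, function(nsd) {
    coh <- generate_cohort(synth_config(num_subjects = 2, duration_s = 20,
                                        sampling_rate_hz = 128,
                                        noise_sd = nsd, seed = 37))
    mean(vapply(1:2, function(i) {
      pk <- detect_rpeaks(preprocess_record(coh$records[[i]]))
      rpeak_match_stats(pk, coh$r_peaks[[i]], 128)$f1
    }, numeric(1)))
  }, numeric(1))
  expect_equal(f1s[1], 1)
  expect_lt(f1s[5], f1s[1])
  expect_true(all(diff(f1s) <= 1e-9))  # non-increasing across the sweep
})

test_that("noise-free beat shapes separate subjects with a centroid classifier", {
  coh <- generate_cohort(synth_config(num_subjects = 6, duration_s = 30,
                                      sampling_rate_hz = 128, noise_sd = 0,
                                      baseline_wander_amp = 0, seed = 8))
  nc <- nearest_centroid_check(coh)
  expect_equal(nc$accuracy, 1)
})

test_that("the SNR helper hits the requested signal-to-noise ratio", {
  cfg <- synth_config(duration_s = 20, sampling_rate_hz = 128, seed = 14)
  m <- sample_subject(14, 1)
  nsd <- noise_sd_for_snr(m, cfg, 10)
  clean_cfg <- cfg; clean_cfg$noise_sd <- 0; clean_cfg$baseline_wander_amp <- 0
  clean <- generate_record(m, clean_cfg)$record$samples
  expect_equal(10 * log10(mean(clean^2) / nsd^2), 10, tolerance = 1e-8)
})
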