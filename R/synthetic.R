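#' Synthetic cohort configuration
#'
#' Parameters for the multi-subject synthetic ECG generator. Each record is a
#' train of heartbeats, one beat being the sum of five Gaussian bumps (P, Q,
#' R, S, T waves) at subject-specific amplitudes, widths and phase offsets,
#' with Gaussian inter-beat variability, sinusoidal baseline wander and white
#' Gaussian noise on top. Ground-truth R-peak sample positions are returned
#' with every record, which is what makes the detector and the end-to-end
#' classifier testable without any real recordings.
#'
#' @param num_subjects Number of subjects in the cohort.
#' @param duration_s Record duration in seconds.
#' @param sampling_rate_hz Sampling rate; 128 and 360 Hz mirror the rates of
#'   the two public MIT-BIH databases the pipeline targets.
#' @param noise_sd Standard deviation of the additive white noise (signal
#'   units).
#' @param baseline_wander_amp Amplitude of the sinusoidal baseline wander.
#' @param baseline_wander_hz Frequency of the baseline wander (default
#'   0.25 Hz, respiratory range).
#' @param seed Integer seed; every draw in the generator is derived from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(num_subjects = 6L, duration_s = 60,
                         sampling_rate_hz = 360, noise_sd = 0.05,
                         baseline_wander_amp = 0.08,
                         baseline_wander_hz = 0.25, seed = 1L) {
  stopifnot(num_subjects >= 1, duration_s > 0, sampling_rate_hz > 0,
            noise_sd >= 0, baseline_wander_amp >= 0, baseline_wander_hz > 0)
  structure(list(num_subjects = as.integer(num_subjects),
                 duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 noise_sd = noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_hz = baseline_wander_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# evaluate expr with a private RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uniform ranges for the per-subject wave parameters; offsets are phase
# angles (radians) within one nominal cardiac cycle, R at 0
wave_param_ranges <- function() {
  list(
    #          amp_lo amp_hi width_lo width_hi off_lo  off_hi   (widths/offsets in s)
    P = list(a = c( 0.10,  0.25), b = c(0.020, 0.035), off = c(-0.260, -0.170)),
    Q = list(a = c(-0.16, -0.06), b = c(0.008, 0.015), off = c(-0.048, -0.032)),
    R = list(a = c( 0.90,  1.60), b = c(0.008, 0.014), off = c( 0.000,  0.000)),
    S = list(a = c(-0.32, -0.10), b = c(0.008, 0.015), off = c( 0.032,  0.048)),
    T = list(a = c( 0.20,  0.45), b = c(0.040, 0.070), off = c( 0.190,  0.300)))
}

#' Draw a subject's beat morphology
#'
#' Deterministically derives one subject's wave parameters (amplitude, width
#' and within-cycle phase for each of the P, Q, R, S and T waves, plus mean
#' heart rate) from a cohort seed and a subject index. The uniform ranges are
#' wide enough that beat shapes differ more between subjects than within one
#' subject's record — the premise that makes ECG-based identification
#' possible — while always keeping the R wave the largest deflection and the
#' waves in their physiological P < Q < R < S < T order.
#'
#' @param seed Cohort seed.
#' @param index Subject index (1-based).
#' @param mean_hr_bpm,hr_sd_bpm Optional overrides for the subject's mean
#'   heart rate and its beat-to-beat standard deviation; by default the mean
#'   is drawn from U(55, 85) bpm and the SD is 2 bpm.
#' @return An object of class `subject_morphology` with fields `waves` (5 x 3
#'   matrix of amplitude, width_s, theta), `mean_hr_bpm`, `hr_sd_bpm`.
#' @export
sample_subject <- function(seed, index, mean_hr_bpm = NULL, hr_sd_bpm = 2) {
  ranges <- wave_param_ranges()
  with_seed((as.numeric(seed) * 1000003 + as.numeric(index)) %% 2147483647, {
    hr <- if (is.null(mean_hr_bpm)) stats::runif(1, 55, 85) else mean_hr_bpm
    cycle_s <- 60 / hr
    waves <- t(vapply(ranges, function(r) {
      c(amplitude = stats::runif(1, r$a[1], r$a[2]),
        width_s   = stats::runif(1, r$b[1], r$b[2]),
        # phase within the nominal cycle, radians; R fixed at 0
        theta     = 2 * pi * stats::runif(1, r$off[1], r$off[2]) / cycle_s)
    }, numeric(3)))
    structure(list(waves = waves, mean_hr_bpm = hr, hr_sd_bpm = hr_sd_bpm),
              class = "subject_morphology")
  })
}

#' @export
print.subject_morphology <- function(x, ...) {
  cat(sprintf("<subject_morphology> mean HR %.1f bpm (sd %.1f)\n",
              x$mean_hr_bpm, x$hr_sd_bpm))
  print(round(x$waves, 4))
  invisible(x)
}

# RR intervals (seconds): Gaussian around 60/hr, clamped at the 0.2 s
# clinical floor (no admissible rhythm exceeds 300 bpm)
sample_rr_intervals <- function(n, mean_hr_bpm, hr_sd_bpm) {
  mean_rr <- 60 / mean_hr_bpm
  sd_rr <- hr_sd_bpm * 60 / mean_hr_bpm^2  # delta-method sd on the RR scale
  pmax(stats::rnorm(n, mean_rr, sd_rr), 0.2)
}

#' Generate one synthetic ECG record
#'
#' Renders a beat train for one subject: R-peak times are laid down with
#' Gaussian RR variability (floored at 0.2 s), each beat is the sum of five
#' Gaussian wave bumps at the subject's offsets, and sinusoidal baseline
#' wander plus white noise are added. The exact R sample positions are
#' returned as ground truth.
#'
#' @param morph A [sample_subject()] morphology.
#' @param config A [synth_config()].
#' @param subject_id Label attached to the record.
#' @param seed Optional seed for this record's noise/RR draws; defaults to
#'   the config seed.
#' @return A list with `record` (an [ecg_record()]) and `r_peaks` (integer
#'   vector of 1-based ground-truth R sample indices).
#' @export
generate_record <- function(morph, config = synth_config(),
                            subject_id = "synthetic", seed = config$seed) {
  stopifnot(inherits(morph, "subject_morphology"))
  fs <- config$sampling_rate_hz
  dur <- config$duration_s
  n <- as.integer(round(dur * fs))
  mean_rr <- 60 / morph$mean_hr_bpm
  if (dur < 0.3 + mean_rr)
    stop("generate_record: duration shorter than one beat at the subject's heart rate")
  with_seed(seed, {
    # beat times: first R at 0.3 s, then cumulative RR; keep beats whose full
    # T wave fits inside the record
    max_beats <- ceiling(dur / 0.2) + 2L
    rr <- sample_rr_intervals(max_beats, morph$mean_hr_bpm, morph$hr_sd_bpm)
    t_r <- 0.3 + c(0, cumsum(rr))
    t_r <- t_r[t_r <= dur - 0.35]
    if (length(t_r) == 0L)
      stop("generate_record: no beats fit in the requested duration")
    t <- (seq_len(n) - 1L) / fs
    cycle_s <- 60 / morph$mean_hr_bpm
    x <- numeric(n)
    for (w in seq_len(nrow(morph$waves))) {
      a <- morph$waves[w, "amplitude"]
      b <- morph$waves[w, "width_s"]
      off <- morph$waves[w, "theta"] * cycle_s / (2 * pi)
      for (tr in t_r) {
        center <- tr + off
        # render only within +/- 5 widths of the bump
        i0 <- max(1L, as.integer(floor((center - 5 * b) * fs)) + 1L)
        i1 <- min(n, as.integer(ceiling((center + 5 * b) * fs)) + 1L)
        if (i0 > i1) next
        idx <- i0:i1
        x[idx] <- x[idx] + a * exp(-((t[idx] - center)^2) / (2 * b^2))
      }
    }
    wander <- config$baseline_wander_amp *
      sin(2 * pi * config$baseline_wander_hz * t)
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    rec <- ecg_record(x + wander + noise, fs, subject_id)
    list(record = rec, r_peaks = as.integer(round(t_r * fs)) + 1L)
  })
}

#' Generate a labelled multi-subject cohort
#'
#' One record per subject, with subject labels `"S01"`, `"S02"`, ... and a
#' ground-truth manifest of every subject's morphology and R-peak positions.
#' Fully deterministic in the config seed.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort` with `records` (list of
#'   [ecg_record()]), `r_peaks` (list of integer vectors), `morphologies`,
#'   and `config`.
#' @examples
#' coh <- generate_cohort(synth_config(num_subjects = 3, duration_s = 15,
#'                                     seed = 7))
#' sapply(coh$records, function(r) r$subject_id)
#' @export
generate_cohort <- function(config = synth_config()) {
  ids <- sprintf("S%02d", seq_len(config$num_subjects))
  morphs <- lapply(seq_len(config$num_subjects),
                   function(i) sample_subject(config$seed, i))
  out <- lapply(seq_len(config$num_subjects), function(i) {
    generate_record(morphs[[i]], config, subject_id = ids[i],
                    seed = (as.numeric(config$seed) * 7919 + i) %% 2147483647)
  })
  structure(list(records = lapply(out, `[[`, "record"),
                 r_peaks = lapply(out, `[[`, "r_peaks"),
                 morphologies = morphs,
                 config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects, %.0f s each @ %g Hz (noise sd %g)\n",
              length(x$records), x$config$duration_s,
              x$config$sampling_rate_hz, x$config$noise_sd))
  invisible(x)
}

#' Noise level for a target signal-to-noise ratio
#'
#' Computes the white-noise standard deviation that gives a requested SNR
#' (in dB) against the clean (noise- and wander-free) rendering of a
#' morphology: `sd = sqrt(mean(clean^2) / 10^(snr_db/10))`.
#'
#' @param morph A [sample_subject()] morphology.
#' @param config A [synth_config()]; its `noise_sd`/wander are ignored for
#'   the clean reference rendering.
#' @param snr_db Target SNR in decibels.
#' @return Noise standard deviation (signal units).
#' @export
noise_sd_for_snr <- function(morph, config, snr_db) {
  clean_cfg <- config
  clean_cfg$noise_sd <- 0
  clean_cfg$baseline_wander_amp <- 0
  clean <- generate_record(morph, clean_cfg)$record$samples
  sqrt(mean(clean^2) / 10^(snr_db / 10))
}
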