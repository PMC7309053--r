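#' Segmentation configuration
#'
#' Controls how a preprocessed record is cut into equal-length classifier
#' input windows: either non-overlapping fixed-duration slices
#' (`"fixed_window"`), or beat windows aligned on detected R peaks and
#' concatenated `group_n` at a time (`"rpeak_grouped"`).
#'
#' @param mode `"fixed_window"` or `"rpeak_grouped"`.
#' @param window_samples Window length in samples for fixed mode (288 at
#'   128 Hz and 444 at 360 Hz are the canonical choices for the two MIT-BIH
#'   databases, i.e. 2.25 s and 1.23 s of signal).
#' @param group_n Number of consecutive beats concatenated into one input
#'   window in R-peak mode (3, 6 or 9 in the reference experiments).
#' @param beat_window_samples Per-beat trim length in samples (R-peak mode).
#' @param beat_pre_frac Fraction of the beat window placed before the R peak
#'   (default 1/3, which keeps both the P and the T wave inside a 444-sample
#'   window at 360 Hz).
#' @param refractory_s Minimum admissible R-R interval in seconds. The
#'   default 0.2 s corresponds to the clinical ceiling of 300 bpm; values
#'   below 0.2 are rejected.
#' @param threshold_frac Detector threshold as a fraction of the local
#'   (rolling ~3 s) maximum of the integrated QRS energy; must separate the
#'   QRS energy hump from the T-wave hump (whose energy is an order of
#'   magnitude lower).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(mode = c("rpeak_grouped", "fixed_window"),
                                window_samples = 288L, group_n = 3L,
                                beat_window_samples = 444L,
                                beat_pre_frac = 1 / 3,
                                refractory_s = 0.2,
                                threshold_frac = 0.3) {
  mode <- match.arg(mode)
  stopifnot(window_samples >= 2, group_n >= 1, beat_window_samples >= 2,
            beat_pre_frac > 0, beat_pre_frac < 1,
            threshold_frac > 0, threshold_frac < 1)
  if (refractory_s < 0.2)
    stop("segmentation_config: refractory_s below the 0.2 s clinical bound (300 bpm)")
  structure(list(mode = mode,
                 window_samples = as.integer(window_samples),
                 group_n = as.integer(group_n),
                 beat_window_samples = as.integer(beat_window_samples),
                 beat_pre_frac = beat_pre_frac,
                 refractory_s = refractory_s,
                 threshold_frac = threshold_frac),
            class = "segmentation_config")
}

#' Duration of an input window
#'
#' @param window_samples Window length in samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Duration in seconds.
#' @examples
#' segment_duration_s(288, 128)  # 2.25
#' segment_duration_s(444, 360)  # 1.2333...
#' @export
segment_duration_s <- function(window_samples, sampling_rate_hz) {
  window_samples / sampling_rate_hz
}

#' Detect R peaks
#'
#' Pan-Tompkins-style detector operating on the output of
#' [preprocess_record()] (a derivative-filtered, smoothed, normalized
#' signal). The signal is squared and integrated over a 150 ms moving
#' window; candidate beats are contiguous regions where the integrated QRS
#' energy exceeds a configurable fraction of its local rolling maximum (the
#' per-beat QRS energy level, tracked over ~3 s so the threshold follows
#' amplitude drift). Within each region the R position is refined to the
#' midpoint of the biphasic lobe pair of the derivative-filtered signal —
#' the point where the underlying R wave itself peaks — and candidates are
#' deduplicated under the refractory rule: of any two peaks closer than
#' `refractory_s`, the one with the larger QRS energy survives.
#'
#' @param record A preprocessed [ecg_record()].
#' @param config A [segmentation_config()].
#' @return Integer vector of strictly increasing 1-based R sample indices
#'   (class `rpeak_list`). Empty on a flat or too-short record.
#' @export
detect_rpeaks <- function(record, config = segmentation_config()) {
  stopifnot_record(record)
  x <- record$samples
  fs <- record$sampling_rate_hz
  n <- length(x)
  refr <- as.integer(round(config$refractory_s * fs))
  if (n < max(refr, 3L)) return(rpeak_list(integer(0)))

  energy <- running_mean(x^2, ma_window_samples(0.15, fs))

  # local QRS energy level: rolling maximum over ~3 s (about 3 beats even at
  # low heart rates), so the threshold adapts to amplitude drift
  local_max <- rolling_max(energy, as.integer(round(1.5 * fs)))
  thr <- config$threshold_frac * local_max + 1e-12
  above <- energy > thr
  if (!any(above)) return(rpeak_list(integer(0)))

  # contiguous supra-threshold regions -> one candidate per region
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  half <- as.integer(round(0.10 * fs))  # refinement half-window, 100 ms
  cand <- apply(regions, 1L, function(reg) {
    peak_e <- reg[1] + which.max(energy[reg[1]:reg[2]]) - 1L
    refine_biphasic_midpoint(x, peak_e, half)
  })
  cand <- sort(unique(as.integer(cand)))
  rpeak_list(enforce_refractory(cand, energy[cand], refr))
}

# The derivative-filtered R wave is biphasic: a positive lobe peaking just
# before the raw R apex and a negative lobe bottoming just after it, placed
# symmetrically. The apex is therefore estimated as the midpoint between the
# positive-lobe maximum and the following negative-lobe minimum — far more
# noise-robust than hunting the zero crossing between them.
refine_biphasic_midpoint <- function(x, center, half) {
  n <- length(x)
  lo <- max(1L, center - half)
  hi <- min(n, center + half)
  if (hi <= lo) return(center)
  imax <- lo + which.max(x[lo:hi]) - 1L
  hi2 <- min(n, imax + half)
  if (hi2 <= imax) return(imax)
  imin <- imax + which.min(x[imax:hi2]) - 1L
  as.integer((imax + imin) %/% 2L)
}

# approximate centered rolling max with half-window `half`: block maxima
# over blocks of size `half`, each sample covered by its own and both
# neighbouring blocks
rolling_max <- function(x, half) {
  n <- length(x)
  if (half >= n) return(rep(max(x), n))
  blk <- ceiling(seq_len(n) / half)
  bmax <- tapply(x, blk, max)
  nb <- length(bmax)
  left <- c(bmax[1], bmax[-nb])
  right <- c(bmax[-1], bmax[nb])
  pmax(left, bmax, right)[blk]
}

# greedy scan: of any two candidates closer than the minimum R-R interval,
# the larger-amplitude one survives
enforce_refractory <- function(cand, amp, refr) {
  keep <- integer(0)
  keep_amp <- numeric(0)
  for (j in seq_along(cand)) {
    p <- cand[j]
    if (length(keep) && p - keep[length(keep)] < refr) {
      if (amp[j] > keep_amp[length(keep)]) {
        keep[length(keep)] <- p
        keep_amp[length(keep)] <- amp[j]
      }
    } else {
      keep <- c(keep, p)
      keep_amp <- c(keep_amp, amp[j])
    }
  }
  keep
}

#' R-peak index list
#'
#' @param indices Strictly increasing integer sample positions.
#' @return Integer vector of class `rpeak_list`.
#' @export
rpeak_list <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L))
    stop("rpeak_list: indices must be strictly increasing")
  structure(indices, class = "rpeak_list")
}

#' Labelled set of equal-length input windows
#'
#' @param windows Numeric matrix, one row per window.
#' @param labels Subject label per window.
#' @param source_rate_hz Sampling rate of the source records.
#' @param mode Segmentation mode that produced the set.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(windows, labels, source_rate_hz, mode) {
  if (!is.matrix(windows)) windows <- matrix(windows, nrow = 0)
  if (nrow(windows) != length(labels))
    stop("segment_set: one label per window required")
  structure(list(windows = windows, labels = as.character(labels),
                 source_rate_hz = source_rate_hz, mode = mode),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d windows x %d samples (%s mode, %g Hz), %d subject(s)\n",
              nrow(x$windows), ncol(x$windows), x$mode, x$source_rate_hz,
              length(unique(x$labels))))
  invisible(x)
}

#' Combine segment sets
#'
#' @param ... `segment_set` objects with matching window length, rate and
#'   mode.
#' @return A single `segment_set`.
#' @export
bind_segments <- function(...) {
  sets <- Filter(function(s) nrow(s$windows) > 0L, list(...))
  if (length(sets) == 0L) stop("bind_segments: no non-empty sets")
  wl <- unique(vapply(sets, function(s) ncol(s$windows), integer(1)))
  if (length(wl) != 1L)
    stop("bind_segments: window lengths differ")
  segment_set(do.call(rbind, lapply(sets, `[[`, "windows")),
              unlist(lapply(sets, `[[`, "labels")),
              sets[[1]]$source_rate_hz, sets[[1]]$mode)
}

#' Fixed-period segmentation
#'
#' Cuts the record into consecutive non-overlapping windows of exactly
#' `window_samples` samples; a trailing remainder shorter than one window is
#' dropped. Each window carries the record's subject label.
#'
#' @param record A preprocessed [ecg_record()].
#' @param config A [segmentation_config()].
#' @return A [segment_set()] with `floor(length / window_samples)` windows.
#' @export
segment_fixed <- function(record, config = segmentation_config(mode = "fixed_window")) {
  stopifnot_record(record)
  w <- config$window_samples
  n <- length(record$samples)
  count <- n %/% w
  if (count == 0L)
    return(segment_set(matrix(numeric(0), 0, w), character(0),
                       record$sampling_rate_hz, "fixed_window"))
  m <- matrix(record$samples[seq_len(count * w)], nrow = count, ncol = w,
              byrow = TRUE)
  segment_set(m, rep(record$subject_id, count), record$sampling_rate_hz,
              "fixed_window")
}

#' R-peak-aligned grouped segmentation
#'
#' Trims a `beat_window_samples`-long window around every usable R peak
#' (`beat_pre_frac` of it before the peak), discards beats whose window runs
#' off the record, and concatenates consecutive runs of `group_n` beat
#' windows into one classifier input of `group_n * beat_window_samples`
#' samples. Groups are non-overlapping and in temporal order; leftover beats
#' that do not fill a group are dropped.
#'
#' @param record A preprocessed [ecg_record()].
#' @param peaks An [rpeak_list()] (e.g. from [detect_rpeaks()]).
#' @param config A [segmentation_config()].
#' @return A [segment_set()].
#' @export
segment_rpeak_grouped <- function(record, peaks,
                                  config = segmentation_config()) {
  stopifnot_record(record)
  bw <- config$beat_window_samples
  pre <- as.integer(round(config$beat_pre_frac * bw))
  post <- bw - pre
  n <- length(record$samples)
  gl <- config$group_n * bw

  usable <- peaks[peaks - pre >= 1L & peaks + post - 1L <= n]
  n_groups <- length(usable) %/% config$group_n
  if (n_groups == 0L)
    return(segment_set(matrix(numeric(0), 0, gl), character(0),
                       record$sampling_rate_hz, "rpeak_grouped"))
  m <- matrix(0, n_groups, gl)
  for (g in seq_len(n_groups)) {
    beats <- usable[((g - 1L) * config$group_n + 1L):(g * config$group_n)]
    m[g, ] <- unlist(lapply(beats, function(p)
      record$samples[(p - pre):(p + post - 1L)]))
  }
  segment_set(m, rep(record$subject_id, n_groups), record$sampling_rate_hz,
              "rpeak_grouped")
}

#' Split grouped windows back into their component beat windows
#'
#' The inverse of the concatenation step of [segment_rpeak_grouped()]: each
#' window of `group_n * w` samples becomes `group_n` windows of `w` samples
#' carrying the same subject label. Because the classifier's sum-rule late
#' fusion scores a group as the average of its per-step scores, a model can
#' be trained on these shorter per-beat windows — three times the sample
#' count at a third of the back-propagation depth — and still be evaluated
#' on the full grouped windows.
#'
#' @param segments A [segment_set()] of grouped windows.
#' @param group_n The group size the windows were built with.
#' @return A [segment_set()] of per-beat windows (in temporal order).
#' @export
split_group_windows <- function(segments, group_n) {
  stopifnot(inherits(segments, "segment_set"))
  gl <- ncol(segments$windows)
  if (gl %% group_n != 0L)
    stop("split_group_windows: window length is not a multiple of group_n")
  bw <- gl %/% group_n
  n <- nrow(segments$windows)
  out <- matrix(0, n * group_n, bw)
  for (g in seq_len(group_n))
    out[seq.int(g, by = group_n, length.out = n), ] <-
      segments$windows[, ((g - 1L) * bw + 1L):(g * bw), drop = FALSE]
  segment_set(out, rep(segments$labels, each = group_n),
              segments$source_rate_hz, segments$mode)
}

#' Segment a record under a configuration
#'
#' Dispatches to [segment_fixed()] or [detect_rpeaks()] +
#' [segment_rpeak_grouped()] according to the config's mode.
#'
#' @inheritParams segment_fixed
#' @return A [segment_set()].
#' @export
segment_record <- function(record, config = segmentation_config()) {
  if (config$mode == "fixed_window") segment_fixed(record, config)
  else segment_rpeak_grouped(record, detect_rpeaks(record, config), config)
}
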