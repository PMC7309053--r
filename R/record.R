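#' Single-channel ECG record
#'
#' Lightweight container for one channel of an ECG recording: an amplitude
#' vector (mV or arbitrary units), its sampling rate, and the identity label
#' of the subject it was recorded from. All pipeline stages consume and emit
#' this structure.
#'
#' @param samples Numeric vector of amplitudes. Must be non-empty and finite.
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param subject_id Opaque subject label (coerced to character).
#' @param channel_index Which channel of a multi-channel source this was
#'   taken from (0-based, informational only).
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 100)), 100, "s1")
#' rec
#' @export
ecg_record <- function(samples, sampling_rate_hz, subject_id = "unknown",
                       channel_index = 0L) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("ecg_record: 'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stop("ecg_record: all samples must be finite")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("ecg_record: 'sampling_rate_hz' must be a positive scalar")
  structure(
    list(samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         subject_id = as.character(subject_id),
         channel_index = as.integer(channel_index)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject '%s': %d samples @ %g Hz (%.2f s), channel %d\n",
              x$subject_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$channel_index))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

is_ecg_record <- function(x) inherits(x, "ecg_record")

stopifnot_record <- function(record) {
  if (!is_ecg_record(record))
    stop("expected an 'ecg_record' object")
  invisible(record)
}
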