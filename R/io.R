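#' Default run configuration
#'
#' The layered configuration defaults: preprocessing spans, segmentation
#' sizes, model architecture, and the reference training settings
#' (cross-entropy, Adam, learning rate 0.001).
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    channel = 0L,
    preprocess = list(ma_window_s = 0.15, derivative = "first_difference"),
    segmentation = list(mode = "rpeak_grouped", window_samples = 288L,
                        group_n = 3L, beat_window_samples = 444L,
                        beat_pre_frac = 1 / 3, refractory_s = 0.2,
                        threshold_frac = 0.3),
    model = list(arch = 6L, hidden = 128L, act_g = "tanh"),
    training = list(learning_rate = 0.001, batch_size = 100L, epochs = 50L,
                    split_fraction = 0.8, seed = 1L, keep_prob = 1),
    synth = list(num_subjects = 6L, duration_s = 60, sampling_rate_hz = 360,
                 noise_sd = 0.05, baseline_wander_amp = 0.08,
                 baseline_wander_hz = 0.25, seed = 1L))
}

# recursive merge rejecting keys absent from the reference structure
merge_config <- function(base, override, path = character(0)) {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop(sprintf("unknown configuration key: %s",
                   paste(c(path, k), collapse = ".")))
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]], c(path, k))
    else override[[k]]
  }
  base
}

#' Load a layered run configuration
#'
#' Resolution order: package defaults, overridden by the YAML file (if
#' given), overridden by explicit values (e.g. parsed command-line flags).
#' Keys not present in [default_config()] are rejected by name, so typos
#' fail loudly instead of silently using a default.
#'
#' @param path Optional YAML file path; an empty or missing-by-choice
#'   (`NULL`) file yields pure defaults.
#' @param overrides Optional named (possibly nested) list applied last.
#' @return The fully resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("load_config: file not found: %s", path))
    from_file <- yaml::read_yaml(path)
    if (length(from_file)) cfg <- merge_config(cfg, from_file)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the architecture descriptor, every weight, the class
#' levels and the training configuration; a save/load round trip is
#' bit-exact.
#'
#' @param model A fitted `drnn`.
#' @param path Destination file.
#' @return `load_model` returns the `drnn`; `save_model` returns the path
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "drnn") || inherits(model, "drnn_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "drnn") && !inherits(model, "drnn_ensemble"))
    stop(sprintf("load_model: %s does not hold a drnn checkpoint", path))
  model
}

#' Save / load a segment set
#'
#' @param segments A [segment_set()].
#' @param path Destination file.
#' @return `read_segments` returns the `segment_set`; `save_segments`
#'   returns the path invisibly.
#' @export
save_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  saveRDS(segments, path)
  invisible(path)
}

#' @rdname save_segments
#' @export
read_segments <- function(path) {
  segments <- readRDS(path)
  if (!inherits(segments, "segment_set"))
    stop(sprintf("read_segments: %s does not hold a segment set", path))
  segments
}
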