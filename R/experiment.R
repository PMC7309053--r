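#' Stratified train/test split of a segment set
#'
#' Splits windows per class at `split_fraction` (default 0.8/0.2), either by
#' seeded random sampling within each class (`"stratified"`) or
#' chronologically (`"temporal"`: the first fraction of each class's windows
#' trains — useful because windows cut from one recording are
#' autocorrelated). Every class lands in both halves: the test side gets at
#' least one window per class, and so does the training side.
#'
#' @param segments A [segment_set()]; every class needs >= 2 windows.
#' @param split_fraction Training fraction in (0, 1).
#' @param seed Seed for the stratified draw.
#' @param method `"stratified"` or `"temporal"`.
#' @return List with `train` and `test` segment sets (disjoint).
#' @export
split_dataset <- function(segments, split_fraction = 0.8, seed = 1L,
                          method = c("stratified", "temporal")) {
  method <- match.arg(method)
  stopifnot(inherits(segments, "segment_set"),
            split_fraction > 0, split_fraction < 1)
  labs <- segments$labels
  counts <- table(labs)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop(sprintf("split_dataset: class(es) %s have fewer than 2 windows",
                 paste(small, collapse = ", ")))
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labs == cl)
      n_tr <- floor(split_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both sides non-empty
      picked <- if (method == "stratified") sort(sample(idx, n_tr))
                else idx[seq_len(n_tr)]
      train_idx <- c(train_idx, picked)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labs), train_idx)
  subset_segments <- function(i)
    segment_set(segments$windows[i, , drop = FALSE], labs[i],
                segments$source_rate_hz, segments$mode)
  list(train = subset_segments(train_idx), test = subset_segments(test_idx))
}

#' Run one end-to-end identification experiment
#'
#' The full pipeline on a set of labelled records: preprocess each record,
#' segment it (fixed windows or R-peak-grouped beats), pool the windows,
#' split stratified per subject, fit the classifier on the training half and
#' score it on the held-out half. Optionally persists everything needed to
#' rerun identically (resolved configuration with seeds, model checkpoint,
#' JSON report) to `out_dir`.
#'
#' @param records List of [ecg_record()]s (>= 2 distinct subjects).
#' @param preprocess_cfg A [preprocess_config()].
#' @param segment_cfg A [segmentation_config()].
#' @param arch Architecture id 1-6 or a [drnn_arch()].
#' @param hidden Hidden units per direction per layer.
#' @param control A [train_config()].
#' @param method `"single"`: one [drnn()] fit on the training windows.
#'   `"grouped_ensemble"` (R-peak-grouped windows only): the
#'   [drnn_fit_grouped()] recipe — an ensemble of fits pre-trained on the
#'   component beat windows and fine-tuned on the groups.
#' @param n_members,finetune_epochs Ensemble settings for
#'   `"grouped_ensemble"`.
#' @param out_dir Optional output directory for the run artefacts.
#' @param verbose Print training progress.
#' @return List of class `ecgid_experiment`: `report` (an `eval_report`),
#'   `model` (a `drnn` or `drnn_ensemble`), `train`/`test` segment sets,
#'   and the configurations used.
#' @export
run_experiment <- function(records,
                           preprocess_cfg = preprocess_config(),
                           segment_cfg = segmentation_config(),
                           arch = 6L, hidden = 128L,
                           control = train_config(),
                           method = c("single", "grouped_ensemble"),
                           n_members = 3L, finetune_epochs = 15L,
                           out_dir = NULL, verbose = FALSE) {
  method <- match.arg(method)
  if (length(unique(vapply(records, `[[`, character(1), "subject_id"))) < 2L)
    stop("run_experiment: need records from at least 2 subjects")
  segs <- do.call(bind_segments, lapply(records, function(r)
    segment_record(preprocess_record(r, preprocess_cfg), segment_cfg)))
  halves <- split_dataset(segs, control$split_fraction, control$seed)
  model <- if (method == "grouped_ensemble") {
    if (segment_cfg$mode != "rpeak_grouped")
      stop("run_experiment: grouped_ensemble needs rpeak_grouped segmentation")
    drnn_fit_grouped(halves$train, group_n = segment_cfg$group_n,
                     arch = arch, hidden = hidden, n_members = n_members,
                     control = control, finetune_epochs = finetune_epochs,
                     verbose = verbose)
  } else {
    drnn(halves$train, arch = arch, hidden = hidden,
         control = control, verbose = verbose)
  }
  report <- evaluate(model, halves$test)
  out <- structure(list(report = report, model = model,
                        train = halves$train, test = halves$test,
                        preprocess_cfg = preprocess_cfg,
                        segment_cfg = segment_cfg, control = control),
                   class = "ecgid_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_echo <- list(preprocess = unclass(preprocess_cfg),
                     segmentation = unclass(segment_cfg),
                     training = unclass(control),
                     method = method)
    jsonlite::write_json(cfg_echo, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    save_model(model, file.path(out_dir, "model.rds"))
    jsonlite::write_json(
      list(overall_accuracy = report$overall_accuracy,
           overall_precision = report$overall_precision,
           overall_recall = report$overall_recall,
           f1_score = report$f1_score,
           per_class_precision = as.list(report$per_class_precision),
           per_class_recall = as.list(report$per_class_recall)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.ecgid_experiment <- function(x, ...) {
  arch <- if (inherits(x$model, "drnn_ensemble"))
    x$model$members[[1]]$arch else x$model$arch
  if (inherits(x$model, "drnn_ensemble"))
    cat(sprintf("End-to-end identification experiment (Arch %d, hidden %d, %d-member ensemble)\n",
                arch$arch_id, arch$hidden, length(x$model$members)))
  else
    cat(sprintf("End-to-end identification experiment (Arch %d, hidden %d)\n",
                arch$arch_id, arch$hidden))
  cat(sprintf("  %d train / %d test windows of %d samples\n",
              nrow(x$train$windows), nrow(x$test$windows),
              ncol(x$train$windows)))
  print(x$report)
  invisible(x)
}
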