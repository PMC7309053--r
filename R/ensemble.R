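#' Ensemble of recurrent identification models
#'
#' Bundles independently trained `drnn` fits (typically the same
#' architecture trained from different initialization seeds) into one
#' classifier whose class probabilities are the average of the members'.
#' Averaging over independently initialized fits is the standard way to
#' stabilise small-data neural classifiers: member-to-member generalization
#' noise cancels while consistent structure adds up. Members whose final
#' training loss marks them as stalled (above `loss_gate`) are dropped at
#' construction — a decision made on training data alone.
#'
#' @param members List of fitted [drnn()] models sharing one architecture
#'   and class-level set.
#' @param loss_gate Optional training-loss ceiling; members whose best epoch
#'   loss exceeds it are excluded (at least one member is always kept — the
#'   lowest-loss one).
#' @return An object of class `drnn_ensemble`.
#' @export
drnn_ensemble <- function(members, loss_gate = NULL) {
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, logical(1), "drnn")))
  lv <- members[[1]]$class_levels
  for (m in members)
    if (!identical(m$class_levels, lv))
      stop("drnn_ensemble: members disagree on class levels")
  best_losses <- vapply(members, function(m) min(m$loss_trace), numeric(1))
  if (!is.null(loss_gate)) {
    keep <- best_losses <= loss_gate
    if (!any(keep)) keep <- best_losses == min(best_losses)
    members <- members[keep]
    best_losses <- best_losses[keep]
  }
  structure(list(members = members, class_levels = lv,
                 member_losses = best_losses),
            class = "drnn_ensemble")
}

#' @export
print.drnn_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d recurrent identification model(s)\n",
              length(x$members)))
  cat(sprintf("  member best losses: %s\n",
              paste(sprintf("%.3f", x$member_losses), collapse = ", ")))
  cat(sprintf("  classes: %s\n", paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' @describeIn drnn_ensemble Average the members' class probabilities and
#'   (for `type = "class"`) take the argmax.
#' @param object A `drnn_ensemble`.
#' @param newdata A [segment_set()] or windows matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.drnn_ensemble <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- NULL
  for (m in object$members) {
    p <- predict(m, newdata, type = "prob")
    probs <- if (is.null(probs)) p else probs + p
  }
  probs <- probs / length(object$members)
  if (type == "prob") return(probs)
  object$class_levels[apply(probs, 1L, which.max)]
}

#' Two-stage ensemble fit for grouped heartbeat windows
#'
#' The training recipe used for the package's identification studies on
#' grouped beat windows. For each ensemble member (a distinct derived
#' initialization seed): (1) pre-train on the individual beat windows
#' obtained by un-concatenating the training groups with
#' [split_group_windows()] — `group_n` times the samples at 1/`group_n` of
#' the back-propagation depth, which converges quickly and reliably;
#' (2) fine-tune on the full grouped windows, warm-started, so the training
#' objective ends exactly where evaluation happens. Under sum-rule late
#' fusion both stages optimise the same per-step discriminability, which is
#' why the warm start lands in a good basin essentially always. Members
#' that still end stalled are dropped by the ensemble's loss gate.
#'
#' @param train_set A [segment_set()] of grouped windows (length
#'   `group_n * beat_window`).
#' @param group_n Beats per group.
#' @param arch,hidden Architecture id (or [drnn_arch()]) and width.
#' @param n_members Ensemble size.
#' @param control A [train_config()]; used for the pre-training stage, with
#'   the member index folded into the seed.
#' @param finetune_epochs Epochs for the grouped-window stage.
#' @param verbose Print member progress.
#' @return A [drnn_ensemble()].
#' @export
drnn_fit_grouped <- function(train_set, group_n, arch = 6L, hidden = 32L,
                             n_members = 3L, control = train_config(),
                             finetune_epochs = 25L, verbose = FALSE) {
  beats <- split_group_windows(train_set, group_n)
  n_classes <- length(unique(train_set$labels))
  members <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    ctl_pre <- control
    ctl_pre$seed <- as.integer((control$seed + (k - 1L) * 20011) %% 2147483647)
    pre <- drnn(beats, arch = arch, hidden = hidden, control = ctl_pre,
                verbose = verbose)
    ctl_ft <- ctl_pre
    ctl_ft$epochs <- as.integer(finetune_epochs)
    ctl_ft$restarts <- 0L
    members[[k]] <- drnn(train_set, arch = pre$arch, control = ctl_ft,
                         init = pre, verbose = verbose)
    if (verbose)
      message(sprintf("member %d: best loss %.4f", k,
                      min(members[[k]]$loss_trace)))
  }
  drnn_ensemble(members, loss_gate = 0.45 * log(n_classes))
}
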