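#' Training configuration
#'
#' Hyperparameters of the training harness. The defaults are the reference
#' settings: cross-entropy loss, Adam with learning rate 0.001, mini-batch
#' size 100 (1000 is the fixed-window experiments' setting), an 80/20
#' train/test split, and keep-probability 1 (no dropout). Epoch count is the
#' package's own choice (50 with plateau early stopping).
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param split_fraction Training fraction for [split_dataset()].
#' @param seed Seed for shuffling, initialization and dropout.
#' @param keep_prob Keep-probability of the inverted dropout applied to the
#'   top-layer representation; 1 disables dropout.
#' @param patience Early stopping: epochs without a `min_delta` improvement
#'   of the epoch loss before training halts.
#' @param min_delta Minimum loss improvement that counts as progress.
#' @param converge_loss Stop early once the epoch loss falls below this.
#' @param lr_decay Factor applied to the learning rate after `decay_patience`
#'   epochs without improvement (reduce-on-plateau; damps the oscillations
#'   Adam develops near a minimum on long sequences). 1 disables the decay.
#' @param decay_patience Epochs without improvement before the decay fires.
#' @param clip_norm Global gradient-norm clipping threshold (stabilises long
#'   back-propagation-through-time chains).
#' @param chunk_size Windows per compiled-kernel call; gradients are
#'   accumulated across chunks so this only bounds memory, not the result.
#' @param precision `"single"` (default: float32 arithmetic in the training
#'   kernel, the standard precision for recurrent network training) or
#'   `"double"`. Scoring through [predict.drnn()] always runs in double.
#' @param restarts Maximum number of additional training attempts (from a
#'   derived initialization seed) when a fit ends stalled, i.e. with best
#'   loss above `restart_frac * log(num_classes)`. Non-convex recurrent
#'   fits occasionally start in a basin that never sorts all classes;
#'   restarting is the standard remedy (compare `nstart` in k-means). The
#'   attempt with the lowest training loss is kept. 0 disables restarts.
#' @param restart_frac Stall threshold as a fraction of the uniform-softmax
#'   loss `log(num_classes)`.
#' @param stall_epoch,stall_loss Optional early abort for doomed attempts:
#'   if the epoch loss still exceeds `stall_loss` at epoch `stall_epoch`,
#'   the attempt is abandoned immediately (instead of running out the full
#'   epoch budget) so a restart can begin. `stall_epoch = NULL` disables
#'   the check.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 100L,
                         epochs = 50L, split_fraction = 0.8, seed = 1L,
                         keep_prob = 1, patience = 8L, min_delta = 1e-4,
                         converge_loss = 1e-3, lr_decay = 0.5,
                         decay_patience = 3L, clip_norm = 5,
                         chunk_size = 32L, precision = c("single", "double"),
                         restarts = 0L, restart_frac = 0.45,
                         stall_epoch = NULL, stall_loss = 1) {
  precision <- match.arg(precision)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            split_fraction > 0, split_fraction < 1,
            keep_prob > 0, keep_prob <= 1, clip_norm > 0, chunk_size >= 1,
            lr_decay > 0, lr_decay <= 1, decay_patience >= 1,
            restarts >= 0, restart_frac > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 split_fraction = split_fraction, seed = as.integer(seed),
                 keep_prob = keep_prob, patience = as.integer(patience),
                 min_delta = min_delta, converge_loss = converge_loss,
                 lr_decay = lr_decay,
                 decay_patience = as.integer(decay_patience),
                 clip_norm = clip_norm, chunk_size = as.integer(chunk_size),
                 precision = precision, restarts = as.integer(restarts),
                 restart_frac = restart_frac,
                 stall_epoch = if (!is.null(stall_epoch)) as.integer(stall_epoch),
                 stall_loss = stall_loss),
            class = "train_config")
}

# loss (+ gradient) over a set of windows, accumulated over memory-bounded
# chunks; x is T x N (one window per column), y0 0-based labels
batch_loss_grad <- function(theta, arch, x, y0, want_grad, keep_prob,
                            chunk_size, single_prec = FALSE) {
  n <- ncol(x)
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  loss <- 0
  grad <- if (want_grad) numeric(length(theta)) else NULL
  top <- if (arch$bidirectional) 2L * arch$hidden else arch$hidden
  for (idx in idx_chunks) {
    mask <- if (keep_prob < 1)
      matrix(stats::rbinom(top * length(idx), 1L, keep_prob), top, length(idx))
    else matrix(numeric(0), 0, 0)
    res <- cpp_drnn_batch(theta, arch, x[, idx, drop = FALSE],
                          as.integer(y0[idx]), want_grad, mask, keep_prob,
                          single_prec)
    w <- length(idx) / n
    loss <- loss + w * res$loss
    if (want_grad) grad <- grad + w * res$grad
  }
  list(loss = loss, grad = grad)
}

#' Fit the recurrent ECG identification model
#'
#' Trains a stacked (bi)directional LSTM classifier on a labelled
#' [segment_set()] by minimizing the mean cross-entropy of the softmaxed
#' fused window scores with Adam (beta1 = 0.9, beta2 = 0.999,
#' epsilon = 1e-8) over shuffled seeded mini-batches. Windows are fed one
#' scalar sample per time step. Training is deterministic given the seed and
#' single-threaded BLAS.
#'
#' @param segments A [segment_set()] of training windows.
#' @param arch Architecture id 1-6 (see [drnn_arch()]) or a ready
#'   `drnn_arch` object.
#' @param hidden Hidden units per direction per layer (ignored when `arch`
#'   is a `drnn_arch`).
#' @param act_g Modulation-gate activation.
#' @param control A [train_config()].
#' @param init Optional flat parameter vector (or fitted `drnn`) to warm
#'   start from — e.g. fine-tuning on grouped windows a model first trained
#'   on single beats. With a warm start no restarts are attempted.
#' @param verbose Print the per-epoch loss.
#' @return An object of class `drnn` with elements `arch`, `theta` (flat
#'   weight vector), `class_levels`, `loss_trace` (per-epoch mean training
#'   loss), `epochs_run`, and `control`.
#' @seealso [predict.drnn()], [evaluate()], [run_experiment()]
#' @examples
#' \donttest{
#' coh <- generate_cohort(synth_config(num_subjects = 2, duration_s = 20,
#'                                     sampling_rate_hz = 128, seed = 3))
#' segs <- do.call(bind_segments, lapply(coh$records, function(r)
#'   segment_record(preprocess_record(r),
#'                  segmentation_config(beat_window_samples = 128))))
#' fit <- drnn(segs, arch = 4, hidden = 8,
#'             control = train_config(epochs = 10, batch_size = 16))
#' fit
#' }
#' @export
drnn <- function(segments, arch = 6L, hidden = 128L,
                 act_g = c("tanh", "sigmoid"),
                 control = train_config(), init = NULL, verbose = FALSE) {
  stopifnot(inherits(segments, "segment_set"))
  act_g <- match.arg(act_g)
  labels <- factor(segments$labels)
  if (nlevels(labels) < 2L)
    stop("drnn: training requires at least 2 subject classes")
  y0 <- as.integer(labels) - 1L
  if (!inherits(arch, "drnn_arch"))
    arch <- drnn_arch(arch, hidden = hidden, num_classes = nlevels(labels),
                      act_g = act_g)
  if (arch$num_classes != nlevels(labels))
    stop("drnn: architecture num_classes does not match the data")
  x <- t(segments$windows)  # T x N
  n <- ncol(x)

  if (inherits(init, "drnn")) init <- init$theta
  if (!is.null(init) && length(init) != n_params(arch))
    stop("drnn: 'init' does not match the architecture's parameter count")

  one_attempt <- function(attempt_seed) {
    theta <- if (is.null(init)) drnn_init(arch, attempt_seed) else init
    m <- numeric(length(theta)); v <- numeric(length(theta))
    step <- 0L
    trace <- numeric(0)
    best <- Inf; best_theta <- theta; stall <- 0L; decay_stall <- 0L
    lr <- control$learning_rate
    with_seed(attempt_seed, {
      for (epoch in seq_len(control$epochs)) {
        ord <- sample.int(n)
        batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
        ep_loss <- 0
        for (b in batches) {
          lg <- batch_loss_grad(theta, arch, x[, b, drop = FALSE], y0[b],
                                TRUE, control$keep_prob, control$chunk_size,
                                control$precision == "single")
          g <- lg$grad
          gn <- sqrt(sum(g^2))
          if (gn > control$clip_norm) g <- g * (control$clip_norm / gn)
          step <- step + 1L
          m <- 0.9 * m + 0.1 * g
          v <- 0.999 * v + 0.001 * g^2
          mhat <- m / (1 - 0.9^step)
          vhat <- v / (1 - 0.999^step)
          theta <- theta - lr * mhat / (sqrt(vhat) + 1e-8)
          ep_loss <- ep_loss + lg$loss * length(b) / n
        }
        trace <- c(trace, ep_loss)
        if (verbose)
          message(sprintf("epoch %3d  loss %.5f", epoch, ep_loss))
        if (ep_loss < best - control$min_delta) {
          best <- ep_loss; best_theta <- theta
          stall <- 0L; decay_stall <- 0L
        } else {
          stall <- stall + 1L
          decay_stall <- decay_stall + 1L
        }
        if (control$lr_decay < 1 && is.finite(best) &&
            ep_loss > 1.25 * best) {
          # loss spiked well above the best seen (instability on long BPTT
          # chains): backtrack to the best weights, cool the optimizer,
          # halve the learning rate, and resume
          theta <- best_theta
          m[] <- 0; v[] <- 0; step <- 0L
          lr <- lr * control$lr_decay
          decay_stall <- 0L
          if (verbose)
            message(sprintf("  spike: backtracking, learning rate -> %g", lr))
        } else if (control$lr_decay < 1 &&
                   decay_stall >= control$decay_patience) {
          lr <- lr * control$lr_decay
          decay_stall <- 0L
          if (verbose) message(sprintf("  plateau: learning rate -> %g", lr))
        }
        if (ep_loss < control$converge_loss || stall >= control$patience)
          break
        if (!is.null(control$stall_epoch) && epoch >= control$stall_epoch &&
            best > control$stall_loss) {
          if (verbose)
            message(sprintf("  no traction by epoch %d (best %.4f): aborting attempt",
                            epoch, best))
          break
        }
      }
    })
    # keep the best-loss weights, not whatever the last (possibly
    # post-spike) update left behind
    list(theta = best_theta, trace = trace, best = best)
  }

  stall_threshold <- control$restart_frac * log(arch$num_classes)
  fit <- one_attempt(control$seed)
  attempt <- 0L
  if (!is.null(init)) attempt <- control$restarts  # no restarts on warm start
  while (fit$best > stall_threshold && attempt < control$restarts) {
    attempt <- attempt + 1L
    if (verbose)
      message(sprintf("stalled at loss %.4f: restart %d", fit$best, attempt))
    retry <- one_attempt((control$seed + attempt * 10007L) %% 2147483647L)
    if (retry$best < fit$best) fit <- retry
  }

  structure(list(arch = arch, theta = fit$theta,
                 class_levels = levels(labels),
                 loss_trace = fit$trace, epochs_run = length(fit$trace),
                 control = control,
                 source_rate_hz = segments$source_rate_hz,
                 window_samples = nrow(x),
                 call = match.call()),
            class = "drnn")
}

#' Mean cross-entropy of a model on a segment set
#'
#' @param model A `drnn` object.
#' @param segments A [segment_set()] whose labels are a subset of the
#'   model's class levels.
#' @return Mean cross-entropy (nats).
#' @export
drnn_loss <- function(model, segments) {
  y0 <- match(segments$labels, model$class_levels) - 1L
  if (anyNA(y0)) stop("drnn_loss: unseen class label")
  batch_loss_grad(model$theta, model$arch, t(segments$windows), y0,
                  FALSE, 1, model$control$chunk_size,
                  model$control$precision == "single")$loss
}

#' Predict subject identities for new windows
#'
#' Runs the compiled forward pass, fuses the per-timestep scores under the
#' model's fusion rule, and returns classes, probabilities or raw fused
#' scores. Ties are broken toward the lowest class index.
#'
#' @param object A fitted `drnn`.
#' @param newdata A [segment_set()] or a windows matrix (one row per
#'   window). The recurrent stack is length-agnostic, so the windows need
#'   not match the training length — under late fusion the score is the
#'   per-step average either way (a model trained on single beats scores
#'   grouped multi-beat windows directly).
#' @param type `"class"`, `"prob"` or `"score"`.
#' @param ... Unused.
#' @return A character vector of class labels, or an `n x num_classes`
#'   matrix of probabilities / scores with class-level column names.
#' @export
predict.drnn <- function(object, newdata,
                         type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  win <- if (inherits(newdata, "segment_set")) newdata$windows
         else as.matrix(newdata)
  if (ncol(win) < 1L)
    stop("predict.drnn: empty windows")
  x <- t(win)
  n <- ncol(x)
  scores <- matrix(0, object$arch$num_classes, n)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / object$control$chunk_size))) {
    res <- cpp_drnn_batch(object$theta, object$arch, x[, idx, drop = FALSE],
                          integer(0), FALSE, matrix(numeric(0), 0, 0), 1)
    scores[, idx] <- res$scores
  }
  if (type == "score") {
    out <- t(scores)
  } else if (type == "prob") {
    out <- t(apply(scores, 2L, softmax_prob))
  } else {
    return(object$class_levels[apply(scores, 2L, which.max)])
  }
  colnames(out) <- object$class_levels
  out
}

#' @export
print.drnn <- function(x, ...) {
  cat("Recurrent ECG identification model\n")
  print(x$arch)
  cat(sprintf("  %d parameters, trained %d epoch(s), final loss %.5f\n",
              length(x$theta), x$epochs_run,
              x$loss_trace[length(x$loss_trace)]))
  cat(sprintf("  classes: %s\n", paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' @export
summary.drnn <- function(object, ...) {
  shapes <- param_shapes(object$arch)
  structure(list(arch = object$arch,
                 n_params = length(object$theta),
                 blocks = data.frame(
                   block = names(shapes),
                   rows = vapply(shapes, `[`, integer(1), 1L),
                   cols = vapply(shapes, `[`, integer(1), 2L),
                   row.names = NULL),
                 epochs_run = object$epochs_run,
                 initial_loss = object$loss_trace[1],
                 final_loss = object$loss_trace[length(object$loss_trace)],
                 class_levels = object$class_levels),
            class = "summary.drnn")
}

#' @export
print.summary.drnn <- function(x, ...) {
  print(x$arch)
  cat(sprintf("%d trainable parameters in %d blocks\n", x$n_params,
              nrow(x$blocks)))
  cat(sprintf("loss: %.5f (epoch 1) -> %.5f (epoch %d)\n",
              x$initial_loss, x$final_loss, x$epochs_run))
  invisible(x)
}

#' @describeIn drnn Extract the weight blocks (per-layer/direction gate
#'   matrices in packed `[i|f|g|o]` column order, plus the output
#'   projection) as a named list of matrices.
#' @param object A fitted `drnn`.
#' @param ... Unused.
#' @export
coef.drnn <- function(object, ...) {
  unpack_theta(object$theta, object$arch)
}

#' @export
plot.drnn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean training cross-entropy",
                 main = sprintf("Arch %d training loss", x$arch$arch_id), ...)
  invisible(x)
}
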