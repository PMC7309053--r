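sigmoid <- function(z) 1 / (1 + exp(-z))

#' LSTM cell parameters
#'
#' The weight triples of one LSTM cell: for each of the four gates —
#' input (i), output (o), forget (f) and input-modulation (g) — an
#' input-to-gate matrix `U` (input_dim x hidden), a hidden-to-gate matrix
#' `W` (hidden x hidden) and a bias `b` (hidden). The modulation gate's
#' activation is tanh by default (sigmoid selectable).
#'
#' @param Ui,Wi,bi,Uo,Wo,bo,Uf,Wf,bf,Ug,Wg,bg Gate weights and biases.
#' @param activation_g `"tanh"` or `"sigmoid"` for the modulation gate.
#' @return An object of class `lstm_cell_params`.
#' @export
lstm_cell_params <- function(Ui, Wi, bi, Uo, Wo, bo, Uf, Wf, bf, Ug, Wg, bg,
                             activation_g = c("tanh", "sigmoid")) {
  activation_g <- match.arg(activation_g)
  Us <- list(Ui = Ui, Uo = Uo, Uf = Uf, Ug = Ug)
  Ws <- list(Wi = Wi, Wo = Wo, Wf = Wf, Wg = Wg)
  bs <- list(bi = bi, bo = bo, bf = bf, bg = bg)
  H <- length(bi)
  din <- nrow(as.matrix(Ui))
  for (U in Us)
    if (!all(dim(as.matrix(U)) == c(din, H)))
      stop("lstm_cell_params: U matrices must all be input_dim x hidden")
  for (W in Ws)
    if (!all(dim(as.matrix(W)) == c(H, H)))
      stop("lstm_cell_params: W matrices must all be hidden x hidden")
  for (b in bs)
    if (length(b) != H) stop("lstm_cell_params: biases must have length hidden")
  if (!all(vapply(c(Us, Ws, bs), function(m) all(is.finite(m)), logical(1))))
    stop("lstm_cell_params: all entries must be finite")
  structure(c(lapply(Us, as.matrix), lapply(Ws, as.matrix), bs,
              list(activation_g = activation_g, hidden = H, input_dim = din)),
            class = "lstm_cell_params")
}

#' LSTM cell state
#'
#' @param h Hidden-state vector.
#' @param c Internal (memory) state vector.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(h, c) {
  if (length(h) != length(c)) stop("cell_state: h and c must match in length")
  structure(list(h = as.numeric(h), c = as.numeric(c)), class = "cell_state")
}

#' One LSTM cell step
#'
#' Advances an LSTM cell by one time step. With sigma the logistic sigmoid
#' and `act_g` the modulation activation:
#' \deqn{i_t = \sigma(U_i x_t + W_i h_{t-1} + b_i)}
#' \deqn{o_t = \sigma(U_o x_t + W_o h_{t-1} + b_o)}
#' \deqn{f_t = \sigma(U_f x_t + W_f h_{t-1} + b_f)}
#' \deqn{g_t = act_g(U_g x_t + W_g h_{t-1} + b_g)}
#' \deqn{c_t = f_t \odot c_{t-1} + g_t \odot i_t, \quad
#'       h_t = \tanh(c_t) \odot o_t}
#' The forget gate controls retention of the internal state; saturating it
#' (large positive `b_f`) preserves `c` indefinitely, which is what lets the
#' cell carry information across long ECG windows.
#'
#' @param x_t Input vector at this step (length `input_dim`).
#' @param prev A [cell_state()] holding `h_{t-1}` and `c_{t-1}`.
#' @param params An [lstm_cell_params()].
#' @return The new [cell_state()].
#' @export
lstm_cell_step <- function(x_t, prev, params) {
  stopifnot(inherits(params, "lstm_cell_params"), inherits(prev, "cell_state"))
  if (length(x_t) != params$input_dim || length(prev$h) != params$hidden)
    stop("lstm_cell_step: dimension mismatch")
  x_t <- as.numeric(x_t)
  act_g <- if (params$activation_g == "tanh") tanh else sigmoid
  aff <- function(U, W, b)
    as.numeric(crossprod(U, x_t)) + as.numeric(crossprod(W, prev$h)) + b
  i <- sigmoid(aff(params$Ui, params$Wi, params$bi))
  o <- sigmoid(aff(params$Uo, params$Wo, params$bo))
  f <- sigmoid(aff(params$Uf, params$Wf, params$bf))
  g <- act_g(aff(params$Ug, params$Wg, params$bg))
  c_t <- f * prev$c + g * i
  cell_state(tanh(c_t) * o, c_t)
}

#' Run an LSTM layer over a sequence
#'
#' Iterates one cell over a sequence from zero initial state. The forward
#' direction reads t = 1..T; the backward direction reads t = T..1 and the
#' returned hidden states are re-aligned to input order, so column t of the
#' output always corresponds to input step t.
#'
#' @param inputs Matrix with one column per time step (input_dim x T).
#' @param cell An [lstm_cell_params()].
#' @param direction `"forward"` or `"backward"`.
#' @return Hidden-state matrix (hidden x T), aligned to input order.
#' @export
run_layer <- function(inputs, cell, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  inputs <- as.matrix(inputs)
  T_len <- ncol(inputs)
  if (T_len == 0L) stop("run_layer: empty sequence")
  H <- cell$hidden
  out <- matrix(0, H, T_len)
  state <- cell_state(numeric(H), numeric(H))
  steps <- if (direction == "forward") seq_len(T_len) else rev(seq_len(T_len))
  for (t in steps) {
    state <- lstm_cell_step(inputs[, t], state, cell)
    out[, t] <- state$h
  }
  out
}

#' Architecture registry
#'
#' The six evaluated recurrent architectures: 1-3 are unidirectional LSTM
#' stacks of depth 1-3 classifying from the final time step's projected
#' score; 4-6 are bidirectional stacks of depth 1-3 whose per-timestep
#' forward and backward scores are averaged over the window (sum-rule late
#' fusion) before the softmax.
#'
#' @param arch Architecture id, 1-6.
#' @param hidden Hidden units per direction per layer.
#' @param num_classes Number of subject classes.
#' @param act_g Modulation-gate activation, `"tanh"` (default) or
#'   `"sigmoid"`.
#' @param input_dim Input dimensionality per time step (1: one ECG sample
#'   per step).
#' @return An architecture descriptor of class `drnn_arch`.
#' @export
drnn_arch <- function(arch = 6L, hidden = 128L, num_classes,
                      act_g = c("tanh", "sigmoid"), input_dim = 1L) {
  act_g <- match.arg(act_g)
  if (!arch %in% 1:6) stop("drnn_arch: arch must be in 1..6")
  stopifnot(hidden >= 1, num_classes >= 2, input_dim >= 1)
  bidir <- arch >= 4L
  structure(list(arch_id = as.integer(arch),
                 num_layers = as.integer((arch - 1L) %% 3L + 1L),
                 hidden = as.integer(hidden),
                 bidirectional = bidir,
                 fusion = if (bidir) "late_sum" else "last_step",
                 num_classes = as.integer(num_classes),
                 act_g = act_g,
                 input_dim = as.integer(input_dim)),
            class = "drnn_arch")
}

#' @export
print.drnn_arch <- function(x, ...) {
  cell <- if (x$bidirectional) "BiLstm" else "Lstm"
  tail <- if (x$fusion == "late_sum") "late-fusion-softmax" else "softmax"
  cat(sprintf("<drnn_arch %d> %s-%s | hidden %d, classes %d, act_g %s\n",
              x$arch_id,
              paste(rep(cell, x$num_layers), collapse = "-"), tail,
              x$hidden, x$num_classes, x$act_g))
  invisible(x)
}

# ordered parameter blocks of the flat theta vector; order and gate layout
# [i | f | g | o] must match the C++ kernel exactly
param_shapes <- function(arch) {
  H <- arch$hidden
  dirs <- if (arch$bidirectional) c("f", "b") else "f"
  shapes <- list()
  for (l in seq_len(arch$num_layers)) {
    din <- if (l == 1L) arch$input_dim
           else if (arch$bidirectional) 2L * H else H
    for (d in dirs) {
      pre <- sprintf("l%d%s", l, d)
      shapes[[paste0(pre, "_Wx")]] <- c(din, 4L * H)
      shapes[[paste0(pre, "_Wh")]] <- c(H, 4L * H)
      shapes[[paste0(pre, "_b")]]  <- c(4L * H, 1L)
    }
  }
  top <- if (arch$bidirectional) 2L * H else H
  shapes[["Wout"]] <- c(top, arch$num_classes)
  shapes[["bout"]] <- c(arch$num_classes, 1L)
  shapes
}

n_params <- function(arch) {
  sum(vapply(param_shapes(arch), prod, numeric(1)))
}

#' Initialize model weights
#'
#' Input and projection matrices use Glorot-style uniform fan-based
#' initialization (limit `sqrt(6 / (fan_in + fan_out))`); the recurrent
#' (hidden-to-gate) blocks are initialized orthogonally per gate, the
#' standard choice for recurrent networks because it preserves hidden-state
#' norms across many steps. Biases start at zero except the forget gate's,
#' which starts at 1 so the internal state is retained early in training.
#' Deterministic in the seed.
#'
#' @param arch A [drnn_arch()].
#' @param seed Integer seed.
#' @return Flat numeric parameter vector.
#' @export
drnn_init <- function(arch, seed = 1L) {
  shapes <- param_shapes(arch)
  H <- arch$hidden
  with_seed(seed, {
    unlist(lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (grepl("_b$|bout", nm)) {
        b <- numeric(sh[1])
        if (grepl("_b$", nm)) b[(H + 1L):(2L * H)] <- 1  # forget-gate block
        b
      } else if (grepl("_Wh$", nm)) {
        # one orthogonal H x H block per gate
        as.numeric(vapply(1:4, function(g)
          qr.Q(qr(matrix(stats::rnorm(H * H), H, H))), matrix(0, H, H)))
      } else {
        lim <- sqrt(6 / (sh[1] + sh[2]))
        stats::runif(prod(sh), -lim, lim)
      }
    }), use.names = FALSE)
  })
}

# flat theta -> named list of matrices
unpack_theta <- function(theta, arch) {
  shapes <- param_shapes(arch)
  if (length(theta) != sum(vapply(shapes, prod, numeric(1))))
    stop("unpack_theta: parameter vector has wrong length")
  out <- list()
  pos <- 0L
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    sz <- prod(sh)
    out[[nm]] <- matrix(theta[(pos + 1L):(pos + sz)], sh[1], sh[2])
    pos <- pos + sz
  }
  out
}

# one direction of one layer as spec-style per-gate cell params
layer_cell <- function(params, arch, layer, dir) {
  H <- arch$hidden
  pre <- sprintf("l%d%s", layer, dir)
  Wx <- params[[paste0(pre, "_Wx")]]
  Wh <- params[[paste0(pre, "_Wh")]]
  b <- as.numeric(params[[paste0(pre, "_b")]])
  blk <- function(m, j) m[, ((j - 1L) * H + 1L):(j * H), drop = FALSE]
  bblk <- function(j) b[((j - 1L) * H + 1L):(j * H)]
  # packed gate order is [i | f | g | o]
  lstm_cell_params(Ui = blk(Wx, 1), Wi = blk(Wh, 1), bi = bblk(1),
                   Uo = blk(Wx, 4), Wo = blk(Wh, 4), bo = bblk(4),
                   Uf = blk(Wx, 2), Wf = blk(Wh, 2), bf = bblk(2),
                   Ug = blk(Wx, 3), Wg = blk(Wh, 3), bg = bblk(3),
                   activation_g = arch$act_g)
}

#' Per-timestep class scores (reference forward pass)
#'
#' Runs a window through the recurrent stack and returns the
#' `num_classes x T` matrix of per-timestep class scores. Layers are stacked
#' bottom-up; in bidirectional architectures each layer above the first
#' receives the per-step concatenation of the forward and backward hidden
#' states, and the step score is the projection of the concatenated
#' top-layer state — i.e. the sum of the projected forward and backward
#' scores. This plain-R implementation defines the model semantics; the
#' compiled training kernel is required to agree with it.
#'
#' @param model A fitted/initialized `drnn` object (or any list with
#'   elements `arch` and `theta`).
#' @param window Numeric vector (scalar samples, fed one per time step) or
#'   an `input_dim x T` matrix.
#' @return `num_classes x T` score matrix.
#' @export
forward_pass <- function(model, window) {
  arch <- model$arch
  params <- unpack_theta(model$theta, arch)
  x <- if (is.matrix(window)) window else matrix(window, nrow = 1L)
  if (ncol(x) < 1L) stop("forward_pass: window must have length >= 1")
  inputs <- x
  for (l in seq_len(arch$num_layers)) {
    hf <- run_layer(inputs, layer_cell(params, arch, l, "f"), "forward")
    inputs <- if (arch$bidirectional) {
      hb <- run_layer(inputs, layer_cell(params, arch, l, "b"), "backward")
      rbind(hf, hb)
    } else hf
  }
  crossprod(params$Wout, inputs) + as.numeric(params$bout)
}

#' Sum-rule late fusion
#'
#' Averages a sequence of per-timestep class-score vectors into the single
#' window-level prediction score `Y = (1/T) * sum_t y_t`.
#'
#' @param scores `num_classes x T` matrix (or a vector for T = 1).
#' @return Fused score vector of length `num_classes`.
#' @export
late_fusion <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) == 0L) stop("late_fusion: empty score sequence")
  rowMeans(scores)
}

#' Numerically safe softmax
#'
#' @param y Score vector.
#' @return Probability vector summing to 1; computed with max-subtraction so
#'   large scores cannot overflow.
#' @export
softmax_prob <- function(y) {
  e <- exp(y - max(y))
  e / sum(e)
}

# fused window score under the model's fusion rule
fused_score <- function(model, window) {
  scores <- forward_pass(model, window)
  if (model$arch$fusion == "late_sum") late_fusion(scores)
  else scores[, ncol(scores)]
}

#' Classify one window (reference path)
#'
#' Fuses the per-timestep scores under the model's fusion rule (mean over
#' steps for bidirectional late fusion, final step for unidirectional
#' stacks), applies the softmax, and picks the highest-probability class
#' (ties broken by lowest class index).
#'
#' @inheritParams forward_pass
#' @return List with `probabilities`, `class` (label if the model carries
#'   class levels, else the index), and the fused `score` vector.
#' @export
classify <- function(model, window) {
  y <- fused_score(model, window)
  p <- softmax_prob(y)
  idx <- which.max(p)
  lbl <- if (!is.null(model$class_levels)) model$class_levels[idx] else idx
  list(probabilities = p, class = lbl, score = y)
}
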