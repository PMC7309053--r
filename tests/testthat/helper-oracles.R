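# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit scalar loops, no matrix algebra.

# scalar-loop LSTM step: direct elementwise transcription of the gate
# equations, one hidden unit at a time
oracle_lstm_step <- function(x, h_prev, c_prev, p, act_g = "tanh") {
  H <- length(h_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  gact <- if (act_g == "tanh") tanh else sig
  h <- c_new <- numeric(H)
  for (k in seq_len(H)) {
    aff <- function(U, W, b) {
      s <- b[k]
      for (j in seq_along(x)) s <- s + U[j, k] * x[j]
      for (j in seq_len(H)) s <- s + W[j, k] * h_prev[j]
      s
    }
    i <- sig(aff(p$Ui, p$Wi, p$bi))
    o <- sig(aff(p$Uo, p$Wo, p$bo))
    f <- sig(aff(p$Uf, p$Wf, p$bf))
    g <- gact(aff(p$Ug, p$Wg, p$bg))
    c_new[k] <- f * c_prev[k] + g * i
    h[k] <- tanh(c_new[k]) * o
  }
  list(h = h, c = c_new)
}

random_cell <- function(din, H, act_g = "tanh", scale = 3) {
  rmat <- function(r, c) matrix(stats::runif(r * c, -scale, scale), r, c)
  lstm_cell_params(
    Ui = rmat(din, H), Wi = rmat(H, H), bi = stats::runif(H, -scale, scale),
    Uo = rmat(din, H), Wo = rmat(H, H), bo = stats::runif(H, -scale, scale),
    Uf = rmat(din, H), Wf = rmat(H, H), bf = stats::runif(H, -scale, scale),
    Ug = rmat(din, H), Wg = rmat(H, H), bg = stats::runif(H, -scale, scale),
    activation_g = act_g)
}

# brute-force multi-class metrics from first principles (explicit loops)
oracle_metrics <- function(truth, pred, levels) {
  C <- length(levels)
  N <- length(truth)
  tp <- fp <- fn <- n_c <- numeric(C)
  for (ci in seq_len(C)) {
    for (j in seq_len(N)) {
      t_is <- truth[j] == levels[ci]
      p_is <- pred[j] == levels[ci]
      if (t_is) n_c[ci] <- n_c[ci] + 1
      if (t_is && p_is) tp[ci] <- tp[ci] + 1
      if (!t_is && p_is) fp[ci] <- fp[ci] + 1
      if (t_is && !p_is) fn[ci] <- fn[ci] + 1
    }
  }
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  correct <- 0
  for (j in seq_len(N)) if (truth[j] == pred[j]) correct <- correct + 1
  f1 <- 0
  for (ci in seq_len(C))
    if (prec[ci] + rec[ci] > 0)
      f1 <- f1 + 2 * (n_c[ci] / N) * prec[ci] * rec[ci] / (prec[ci] + rec[ci])
  list(precision = prec, recall = rec, OP = mean(prec), OR = mean(rec),
       OA = correct / N, F1 = f1)
}

# small labelled segment set with per-class amplitude regimes (linearly
# separable by construction)
make_separable_segments <- function(n_per_class = 12, T_len = 40,
                                    classes = c("A", "B"), seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    win <- NULL; labs <- character(0)
    for (ci in seq_along(classes)) {
      level <- (-1)^ci  # +-1 offset regimes
      w <- t(replicate(n_per_class,
                       level + 0.3 * sin(seq_len(T_len) / 3 + stats::runif(1, 0, pi)) +
                         stats::rnorm(T_len, 0, 0.05)))
      win <- rbind(win, w)
      labs <- c(labs, rep(classes[ci], n_per_class))
    }
    segment_set(win, labs, 100, "fixed_window")
  })
}
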