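zero_cell <- function(din = 1, H = 1, act_g = "tanh", bf = 0) {
  z <- function(r, c) matrix(0, r, c)
  lstm_cell_params(Ui = z(din, H), Wi = z(H, H), bi = numeric(H),
                   Uo = z(din, H), Wo = z(H, H), bo = numeric(H),
                   Uf = z(din, H), Wf = z(H, H), bf = rep(bf, H),
                   Ug = z(din, H), Wg = z(H, H), bg = numeric(H),
                   activation_g = act_g)
}

test_that("cell step reproduces hand evaluations of the gate equations", {
  # all zero: gates 0.5, modulation 0 -> state stays 0
  st <- lstm_cell_step(0, cell_state(0, 0), zero_cell())
  expect_equal(st$h, 0)
  expect_equal(st$c, 0)

  # scalar unit-weight case: i = o = f = sigmoid(1), g = tanh(1)
  ones <- lstm_cell_params(Ui = matrix(1), Wi = matrix(1), bi = 0,
                           Uo = matrix(1), Wo = matrix(1), bo = 0,
                           Uf = matrix(1), Wf = matrix(1), bf = 0,
                           Ug = matrix(1), Wg = matrix(1), bg = 0)
  st <- lstm_cell_step(1, cell_state(0, 0), ones)
  s1 <- 1 / (1 + exp(-1))
  expect_equal(st$c, s1 * tanh(1), tolerance = 1e-15)
  expect_equal(st$h, tanh(s1 * tanh(1)) * s1, tolerance = 1e-15)

  # saturated forget gate preserves the internal state
  st <- lstm_cell_step(0, cell_state(0.3, 0.8), zero_cell(bf = 40))
  expect_equal(st$c, 0.8, tolerance = 1e-12)
})

test_that("cell step matches the independent scalar-loop oracle", {
  set.seed(101)
  for (trial in 1:200) {
    din <- sample(1:4, 1); H <- sample(1:4, 1)
    act <- sample(c("tanh", "sigmoid"), 1)
    p <- random_cell(din, H, act)
    x <- runif(din, -3, 3)
    h0 <- runif(H, -1, 1); c0 <- runif(H, -3, 3)
    got <- lstm_cell_step(x, cell_state(h0, c0), p)
    want <- oracle_lstm_step(x, h0, c0, p, act)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("hidden state magnitudes never exceed 1", {
  set.seed(5)
  p <- random_cell(2, 3, scale = 10)
  st <- cell_state(runif(3), runif(3))
  for (t in 1:20) {
    st <- lstm_cell_step(runif(2, -10, 10), st, p)
    expect_true(all(abs(st$h) <= 1))
  }
})

test_that("run_layer directionality: T = 1 symmetric, reversal identity, chaining", {
  set.seed(21)
  cell <- random_cell(2, 3, scale = 1)
  x1 <- matrix(rnorm(2), 2, 1)
  expect_equal(run_layer(x1, cell, "forward"), run_layer(x1, cell, "backward"))

  xs <- matrix(rnorm(10), 2, 5)
  fwd_rev <- run_layer(xs[, 5:1], cell, "forward")[, 5:1]
  expect_equal(run_layer(xs, cell, "backward"), fwd_rev, tolerance = 1e-14)

  # forward equals explicit per-step chaining
  st <- cell_state(numeric(3), numeric(3))
  manual <- matrix(0, 3, 5)
  for (t in 1:5) {
    st <- lstm_cell_step(xs[, t], st, cell)
    manual[, t] <- st$h
  }
  expect_equal(run_layer(xs, cell, "forward"), manual, tolerance = 1e-14)
  expect_error(run_layer(matrix(numeric(0), 2, 0), cell), "empty")
})

test_that("all six registry architectures build and produce shaped scores", {
  win <- rnorm(10)
  for (a in 1:6) {
    arch <- drnn_arch(a, hidden = 3, num_classes = 4)
    expect_equal(arch$num_layers, (a - 1) %% 3 + 1)
    expect_equal(arch$bidirectional, a >= 4)
    mod <- list(arch = arch, theta = drnn_init(arch, a))
    sc <- forward_pass(mod, win)
    expect_equal(dim(sc), c(4L, 10L))
    cl <- classify(mod, win)
    expect_equal(sum(cl$probabilities), 1, tolerance = 1e-12)
    expect_true(all(cl$probabilities > 0 & cl$probabilities < 1))
  }
})

test_that("late fusion is the mean over steps and linear in the scores", {
  v <- c(2, -1, 0.5)
  expect_equal(late_fusion(matrix(v, 3, 7)), v)          # constant scores
  expect_equal(late_fusion(matrix(v, 3, 1)), v)          # T = 1 identity
  expect_equal(late_fusion(cbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(2)
  s <- matrix(rnorm(12), 3, 4); t2 <- matrix(rnorm(12), 3, 4)
  expect_equal(late_fusion(2.5 * s + 4 * t2),
               2.5 * late_fusion(s) + 4 * late_fusion(t2), tolerance = 1e-14)
  expect_error(late_fusion(matrix(numeric(0), 3, 0)), "empty")
})

test_that("softmax is shift-invariant, normalized and overflow-safe", {
  expect_equal(softmax_prob(c(0, 0, 0)), rep(1 / 3, 3))
  p <- softmax_prob(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  y <- rnorm(5)
  expect_equal(softmax_prob(y + 123.4), softmax_prob(y), tolerance = 1e-12)
})

test_that("mirror-symmetric bidirectional models score reversed windows identically", {
  arch <- drnn_arch(4, hidden = 3, num_classes = 3)
  theta <- drnn_init(arch, 99)
  # copy the forward cell into the backward cell, and make the output
  # projection symmetric across the two tracks
  shapes <- ecgid:::param_shapes(arch)
  sizes <- vapply(shapes, prod, numeric(1))
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  blk <- function(nm) starts[[nm]]:ends[[nm]]
  theta[blk("l1b_Wx")] <- theta[blk("l1f_Wx")]
  theta[blk("l1b_Wh")] <- theta[blk("l1f_Wh")]
  theta[blk("l1b_b")] <- theta[blk("l1f_b")]
  W <- matrix(theta[blk("Wout")], 6, 3)
  W[4:6, ] <- W[1:3, ]
  theta[blk("Wout")] <- as.numeric(W)
  mod <- list(arch = arch, theta = theta)
  win <- rnorm(12)
  expect_equal(ecgid:::fused_score(mod, rev(win)),
               ecgid:::fused_score(mod, win), tolerance = 1e-12)
})

test_that("compiled kernel agrees with the plain-R forward pass on every architecture", {
  set.seed(33)
  for (a in 1:6) {
    arch <- drnn_arch(a, hidden = 3, num_classes = 3)
    theta <- drnn_init(arch, a * 7)
    X <- matrix(rnorm(8 * 2), 8, 2)
    mod <- list(arch = arch, theta = theta)
    want <- cbind(ecgid:::fused_score(mod, X[, 1]),
                  ecgid:::fused_score(mod, X[, 2]))
    got <- ecgid:::cpp_drnn_batch(theta, arch, X, integer(0), FALSE,
                                  matrix(numeric(0), 0, 0), 1)$scores
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("compiled gradient matches central finite differences", {
  set.seed(44)
  arch <- drnn_arch(5, hidden = 2, num_classes = 3)
  theta <- drnn_init(arch, 3)
  X <- matrix(rnorm(6 * 2), 6, 2)
  y0 <- c(0L, 2L)
  no_mask <- matrix(numeric(0), 0, 0)
  res <- ecgid:::cpp_drnn_batch(theta, arch, X, y0, TRUE, no_mask, 1)
  eps <- 1e-5
  idx <- sample(length(theta), 60)
  for (j in idx) {
    e <- theta
    e[j] <- e[j] + eps
    up <- ecgid:::cpp_drnn_batch(e, arch, X, y0, FALSE, no_mask, 1)$loss
    e[j] <- e[j] - 2 * eps
    dn <- ecgid:::cpp_drnn_batch(e, arch, X, y0, FALSE, no_mask, 1)$loss
    expect_equal(res$grad[j], (up - dn) / (2 * eps), tolerance = 1e-6)
  }
})

test_that("forget-gate saturation gives the long-memory limit through time", {
  # zero weights, huge forget bias: c is carried unchanged through a layer
  arch <- drnn_arch(1, hidden = 2, num_classes = 2)
  cell <- zero_cell(1, 2, bf = 50)
  st <- cell_state(c(0, 0), c(1.5, -2))
  for (t in 1:30) st <- lstm_cell_step(rnorm(1), st, cell)
  expect_equal(st$c, c(1.5, -2), tolerance = 1e-9)
})
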