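test_that("stratified split honours the fraction and keeps both sides populated", {
  win <- matrix(rnorm(30 * 10), 30, 10)
  labs <- rep(c("a", "b", "c"), each = 10)
  segs <- segment_set(win, labs, 100, "fixed_window")
  h <- split_dataset(segs, 0.8, seed = 4)
  expect_equal(as.numeric(table(h$train$labels)), c(8, 8, 8))
  expect_equal(as.numeric(table(h$test$labels)), c(2, 2, 2))
  # disjoint: windows jointly reconstruct the input set
  expect_equal(nrow(h$train$windows) + nrow(h$test$windows), 30L)

  h2 <- split_dataset(segs, 0.8, seed = 4)
  expect_identical(h$train$windows, h2$train$windows)

  expect_error(split_dataset(segment_set(win[1:11, ], c(rep("a", 10), "b"),
                                         100, "fixed_window")),
               "fewer than 2")
})

test_that("every class size from 2 to 20 leaves at least one window per side", {
  for (n in 2:20) {
    win <- matrix(rnorm(n * 5), n, 5)
    segs <- segment_set(win, rep("a", n), 100, "fixed_window")
    # pair with a second fixed class so the split is well-defined
    segs <- bind_segments(segs, segment_set(matrix(rnorm(20), 4, 5),
                                            rep("b", 4), 100, "fixed_window"))
    h <- split_dataset(segs, 0.8, seed = n)
    expect_gte(sum(h$test$labels == "a"), 1)
    expect_gte(sum(h$train$labels == "a"), 1)
    expect_equal(sum(h$train$labels == "a"),
                 min(max(floor(0.8 * n), 1), n - 1))
  }
})

test_that("temporal split keeps the earliest windows for training", {
  win <- matrix(seq_len(40), 10, 4)   # window i holds value pattern i
  segs <- segment_set(win, rep(c("a", "b"), each = 5), 100, "fixed_window")
  h <- split_dataset(segs, 0.8, seed = 1, method = "temporal")
  expect_equal(h$train$windows[h$train$labels == "a", 1], 1:4)
  expect_equal(h$test$windows[h$test$labels == "a", 1], 5)
})

test_that("initial training loss is close to ln(C) on balanced random classes", {
  set.seed(90)
  segs <- make_separable_segments(n_per_class = 8, T_len = 30,
                                  classes = c("A", "B", "C"), seed = 90)
  # shuffle labels so classes carry no signal and the first-epoch loss sits
  # at the uniform-softmax value
  segs$labels <- sample(segs$labels)
  # a single full batch records the loss before any update
  mod <- drnn(segs, arch = 1, hidden = 4,
              control = train_config(epochs = 1, batch_size = 24, seed = 1))
  expect_equal(mod$loss_trace[1], log(3), tolerance = 0.1)
})

test_that("a separable two-class fixture is learned to perfect training accuracy", {
  segs <- make_separable_segments(n_per_class = 12, T_len = 40, seed = 5)
  mod <- drnn(segs, arch = 4, hidden = 6,
              control = train_config(epochs = 25, batch_size = 8, seed = 5))
  acc <- mean(predict(mod, segs) == segs$labels)
  expect_equal(acc, 1)
  expect_lt(mod$loss_trace[mod$epochs_run], mod$loss_trace[1])
})

test_that("training is reproducible: same seed, same loss trace and weights", {
  segs <- make_separable_segments(n_per_class = 6, T_len = 25, seed = 2)
  ctl <- train_config(epochs = 5, batch_size = 4, seed = 31)
  m1 <- drnn(segs, arch = 4, hidden = 4, control = ctl)
  m2 <- drnn(segs, arch = 4, hidden = 4, control = ctl)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$theta, m2$theta)
  m3 <- drnn(segs, arch = 4, hidden = 4,
             control = train_config(epochs = 5, batch_size = 4, seed = 32))
  expect_false(identical(m3$loss_trace, m1$loss_trace))
})

test_that("dropout keep-probability below 1 still trains", {
  segs <- make_separable_segments(n_per_class = 10, T_len = 30, seed = 6)
  mod <- drnn(segs, arch = 4, hidden = 6,
              control = train_config(epochs = 20, batch_size = 8, seed = 6,
                                     keep_prob = 0.8))
  expect_gte(mean(predict(mod, segs) == segs$labels), 0.9)
})

test_that("labels outside the model's classes are rejected at scoring time", {
  segs <- make_separable_segments(n_per_class = 6, T_len = 25, seed = 3)
  mod <- drnn(segs, arch = 1, hidden = 4,
              control = train_config(epochs = 2, batch_size = 8, seed = 3))
  bad <- segment_set(segs$windows, rep(c("A", "Z"), each = 6), 100,
                     "fixed_window")
  expect_error(drnn_loss(mod, bad), "unseen class")
  # the recurrent stack is length-agnostic: shorter/longer windows score
  pred <- predict(mod, matrix(rnorm(10), 1, 10))
  expect_true(pred %in% c("A", "B"))
})

test_that("model predictions agree with the reference classify() path", {
  segs <- make_separable_segments(n_per_class = 5, T_len = 20, seed = 9)
  mod <- drnn(segs, arch = 5, hidden = 3,
              control = train_config(epochs = 3, batch_size = 5, seed = 9))
  probs <- predict(mod, segs, type = "prob")
  for (i in c(1, 5, 10)) {
    ref <- classify(mod, segs$windows[i, ])
    expect_equal(unname(probs[i, ]), as.numeric(ref$probabilities),
                 tolerance = 1e-10)
  }
})

test_that("ensembles average member probabilities and gate stalled members", {
  segs <- make_separable_segments(n_per_class = 6, T_len = 24, seed = 12)
  m1 <- drnn(segs, arch = 4, hidden = 4,
             control = train_config(epochs = 10, batch_size = 8, seed = 1))
  m2 <- drnn(segs, arch = 4, hidden = 4,
             control = train_config(epochs = 10, batch_size = 8, seed = 2))
  ens <- drnn_ensemble(list(m1, m2))
  p <- predict(ens, segs, type = "prob")
  expect_equal(p, (predict(m1, segs, type = "prob") +
                   predict(m2, segs, type = "prob")) / 2)
  expect_identical(predict(ens, segs),
                   ens$class_levels[apply(p, 1, which.max)])

  # an untrained (high-loss) member is dropped by the gate
  stalled <- drnn(segs, arch = 4, hidden = 4,
                  control = train_config(epochs = 1, batch_size = 24, seed = 3))
  gated <- drnn_ensemble(list(m1, stalled), loss_gate = 0.45 * log(2))
  expect_length(gated$members, 1L)
  # but the best member always survives even if all exceed the gate
  all_bad <- drnn_ensemble(list(stalled), loss_gate = 1e-6)
  expect_length(all_bad$members, 1L)
})

test_that("grouped two-stage fitting trains through beats and fine-tunes on groups", {
  # synthetic grouped windows: 2 classes whose beats live in distinct
  # amplitude regimes, concatenated 2 beats per group
  base <- make_separable_segments(n_per_class = 8, T_len = 40,
                                  classes = c("A", "B"), seed = 13)
  groups <- segment_set(cbind(base$windows, base$windows[, 40:1]),
                        base$labels, 100, "rpeak_grouped")
  ens <- drnn_fit_grouped(groups, group_n = 2, arch = 4, hidden = 4,
                          n_members = 2,
                          control = train_config(epochs = 10, batch_size = 8,
                                                 seed = 21),
                          finetune_epochs = 4)
  expect_s3_class(ens, "drnn_ensemble")
  expect_gte(mean(predict(ens, groups) == groups$labels), 0.9)
})
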