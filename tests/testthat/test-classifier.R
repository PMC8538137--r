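sep_data <- function(n = 120, Tn = 4, Fw = 6, shift = 2, seed = 9) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- array(rnorm(Fw * Tn * n), dim = c(Fw, Tn, n))
  x[1:2, , y == 1] <- x[1:2, , y == 1] + shift
  list(x = x, y = y)
}

small_cfg <- function(sequence_length = 4, ...) {
  model_config(lstm_units = c(8, 6), dense_units = 4,
               sequence_length = sequence_length, ...)
}

test_that("the default architecture stacks 128/32/16 LSTM, dense 8, softmax 2", {
  net <- build_fall_lstm(468, model_config())
  expect_equal(layer_units(net), c(128, 32, 16, 8, 2))
  expect_equal(dim(net$weights$lstm[[1]]$W), c(4 * 128, 468))
  expect_equal(dim(net$weights$lstm[[2]]$W), c(4 * 32, 128))
  expect_equal(dim(net$weights$lstm[[3]]$W), c(4 * 16, 32))
  expect_equal(dim(net$weights$Wd), c(8, 16))
  expect_equal(dim(net$weights$Wo), c(2, 8))
  expect_error(build_fall_lstm(0))
  expect_error(model_config(train_fraction = 1))
  expect_error(model_config(lstm_units = c(0, 4)))
})

test_that("softmax outputs are nonnegative and sum to one; ReLU clips at zero", {
  expect_equal(relu(c(-3, 0, 2)), c(0, 0, 2))
  net <- build_fall_lstm(5, small_cfg(seed = 3))
  x <- array(rnorm(5 * 4 * 20, sd = 5), dim = c(5, 4, 20))
  p <- predict(net, x)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
})

test_that("sequence construction slides within trials only", {
  # synthetic feature matrix: two trials of 12 and 9 windows
  fm <- structure(list(
    x = matrix(seq_len(21 * 2), 21, 2),
    label = c(rep(0L, 11), 1L, rep(0L, 9)),
    activity = rep(c("F1", "FL1"), c(12, 9)),
    subject = rep(1L, 21),
    trial = rep(c("t1", "t2"), c(12, 9)),
    windows = NULL), class = "feature_matrix")
  s <- make_sequences(fm, sequence_length = 10)
  expect_equal(dim(s$x), c(2, 10, 3))   # trial of 12 -> 3; trial of 9 -> 0
  expect_equal(s$trial, rep("t1", 3))
  # sequence label is the final window's label
  expect_equal(s$label, c(0L, 0L, 1L))
  expect_equal(s$x[1, , 3], fm$x[3:12, 1])
  # stride thins the sequence starts
  s2 <- make_sequences(fm, sequence_length = 10, stride = 2)
  expect_equal(dim(s2$x)[3], 2)
})

test_that("analytic gradients match finite differences", {
  d <- sep_data(n = 6, Tn = 3, Fw = 5, seed = 21)
  cfg <- model_config(lstm_units = c(5, 4), dense_units = 3,
                      sequence_length = 3, seed = 8)
  net <- build_fall_lstm(5, cfg)
  cw <- c(1.2, 0.8)
  g <- imufall:::cpp_lstm_grad(net$weights, d$x, d$y, cw)
  getp <- function(w, p) {
    if (p[1] == "lstm") w$lstm[[as.integer(p[2])]][[p[3]]] else w[[p[1]]]
  }
  setp <- function(w, p, val) {
    if (p[1] == "lstm") w$lstm[[as.integer(p[2])]][[p[3]]] <- val
    else w[[p[1]]] <- val
    w
  }
  paths <- list(c("lstm", "1", "W"), c("lstm", "1", "U"), c("lstm", "1", "b"),
                c("lstm", "2", "W"), c("lstm", "2", "U"), c("lstm", "2", "b"),
                "Wd", "bd", "Wo", "bo")
  eps <- 1e-5
  set.seed(4)
  for (p in paths) {
    par <- getp(net$weights, p)
    for (idx in sample(length(par), min(4, length(par)))) {
      pp <- par; pp[idx] <- pp[idx] + eps
      lp <- imufall:::cpp_lstm_grad(setp(net$weights, p, pp), d$x, d$y, cw)$loss
      pm <- par; pm[idx] <- pm[idx] - eps
      lm <- imufall:::cpp_lstm_grad(setp(net$weights, p, pm), d$x, d$y, cw)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- getp(g$grad, p)[idx]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("a zeroed output layer predicts uniformly with loss log(2)", {
  net <- build_fall_lstm(5, small_cfg(seed = 2))
  net$weights$Wo[] <- 0
  net$weights$bo[] <- 0
  d <- sep_data(n = 10, Tn = 4, Fw = 5)
  p <- predict(net, d$x)
  expect_equal(as.vector(p), rep(0.5, 20))
  g <- imufall:::cpp_lstm_grad(net$weights, d$x, d$y, c(1, 1))
  expect_equal(g$loss, log(2), tolerance = 1e-12)
})

test_that("training separates a separable problem and the loss trends downward", {
  d <- sep_data(n = 160, shift = 1.5)
  net <- build_fall_lstm(6, small_cfg(epochs = 50, seed = 5))
  net <- train_fall_lstm(net, d$x, d$y)
  expect_gt(tail(net$history$accuracy, 1), 0.95)
  expect_lt(median(tail(net$history$loss, 10)),
            median(head(net$history$loss, 10)))
  p <- predict(net, d$x)
  expect_gt(mean((p[, "fall"] > 0.5) == d$y), 0.95)
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- sep_data(n = 60)
  cfg <- small_cfg(epochs = 8, seed = 44)
  a <- train_fall_lstm(build_fall_lstm(6, cfg), d$x, d$y)
  b <- train_fall_lstm(build_fall_lstm(6, cfg), d$x, d$y)
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
  # duplicated inputs give identical outputs
  p <- predict(a, d$x[, , c(1, 1, 2), drop = FALSE])
  expect_identical(p[1, ], p[2, ])
})

test_that("degenerate training inputs are rejected", {
  d <- sep_data(n = 20)
  net <- build_fall_lstm(6, small_cfg(epochs = 2))
  expect_error(train_fall_lstm(net, d$x, rep(0L, 20)), "single class")
  expect_error(train_fall_lstm(net, d$x[1:3, , , drop = FALSE], d$y),
               "feature width")
  expect_error(predict(net, d$x[1:3, , , drop = FALSE]), "feature width")
})

test_that("model persistence round-trips bit-identically", {
  d <- sep_data(n = 40)
  net <- train_fall_lstm(build_fall_lstm(6, small_cfg(epochs = 5, seed = 1)),
                         d$x, d$y)
  p0 <- predict(net, d$x)
  path <- tempfile(fileext = ".rds")
  save_fall_lstm(net, path)
  net2 <- read_fall_lstm(path)
  expect_identical(predict(net2, d$x), p0)
  unlink(path)
})

test_that("the high-level fitter splits by trial and evaluates held-out data", {
  feats <- tiny_features()
  cfg <- small_cfg(epochs = 12, sequence_length = 8, seed = 3,
                   standardize = TRUE)
  fit <- fall_lstm(feats, cfg)
  expect_s3_class(fit, "fall_lstm")
  # trial-level split: no trial appears on both sides
  expect_length(intersect(fit$split$train, fit$split$test), 0)
  expect_setequal(c(fit$split$train, fit$split$test), unique(feats$trial))
  expect_true(all(fit$test$prob >= 0 & fit$test$prob <= 1))
  # prediction on the training features has one probability per sequence
  p <- predict(fit, feats)
  expect_true(all(p >= 0 & p <= 1))
  # combination restriction propagates to the network width
  fitc <- fall_lstm(feats, small_cfg(epochs = 3, sequence_length = 8,
                                     seed = 3), combination = "C")
  expect_equal(fitc$net$feature_width, 52)
})
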