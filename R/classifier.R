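# Fall / non-fall sequence classifier: three stacked LSTM layers
# (128/32/16 units), a dense-8 ReLU layer and a 2-unit softmax, trained
# with Adam on sparse categorical cross-entropy.

#' Model configuration
#'
#' Defaults follow the reference training recipe: LSTM stacks of
#' 128/32/16 units, dense ReLU layer of 8 units, softmax over 2
#' classes, Adam with learning rate 0.01, batch size 10, 100 epochs,
#' input sequences of 10 consecutive feature windows (about 1 s of
#' context at the 0.1 s hop), and an 80/20 trial-level train/test
#' split.
#'
#' @param lstm_units integer vector of LSTM layer sizes.
#' @param dense_units dense ReLU layer size.
#' @param n_classes number of output classes.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param sequence_length feature windows per input sequence.
#' @param sequence_stride step between successive sequence starts
#'   within a trial (1 = every start; larger values thin the sequence
#'   set).
#' @param train_fraction fraction of trials used for training (0-1,
#'   exclusive).
#' @param class_weights \code{"balanced"} (inverse-frequency, default)
#'   or a numeric length-\code{n_classes} vector.
#' @param standardize z-score features using training-split statistics
#'   before training (on by default). The windowed statistics span
#'   several orders of magnitude across channels (quaternion components
#'   near 1, Euler means up to 180 degrees), and the wide first LSTM
#'   layer trains unreliably at the 0.01 learning rate without a common
#'   scale.
#' @param max_train_sequences optional cap on the number of training
#'   sequences (stratified, seeded subsample); \code{Inf} keeps all.
#' @param seed integer seed for the split, initialization and batch
#'   shuffling.
#' @return object of class \code{fall_model_config}.
#' @export
model_config <- function(lstm_units = c(128, 32, 16), dense_units = 8,
                         n_classes = 2, learning_rate = 0.01,
                         batch_size = 10, epochs = 100,
                         sequence_length = 10, sequence_stride = 1,
                         train_fraction = 0.8,
                         class_weights = "balanced",
                         standardize = TRUE,
                         max_train_sequences = Inf, seed = 1L) {
  stopifnot(all(lstm_units > 0), dense_units > 0, n_classes >= 2,
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            sequence_length >= 1, sequence_stride >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 sequence_length = as.integer(sequence_length),
                 sequence_stride = as.integer(sequence_stride),
                 train_fraction = train_fraction,
                 class_weights = class_weights,
                 standardize = standardize,
                 max_train_sequences = max_train_sequences,
                 seed = as.integer(seed)),
            class = "fall_model_config")
}

# Glorot-uniform weight list for the network; seeded through the caller
.init_weights <- function(feature_width, config) {
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  nin <- feature_width
  lstm <- vector("list", length(config$lstm_units))
  for (l in seq_along(config$lstm_units)) {
    nh <- config$lstm_units[l]
    b <- rep(0, 4 * nh)
    b[(nh + 1):(2 * nh)] <- 1          # forget-gate bias
    lstm[[l]] <- list(W = glorot(4 * nh, nin, nin, nh),
                      U = glorot(4 * nh, nh, nh, nh),
                      b = b)
    nin <- nh
  }
  list(lstm = lstm,
       Wd = glorot(config$dense_units, nin, nin, config$dense_units),
       bd = rep(0, config$dense_units),
       Wo = glorot(config$n_classes, config$dense_units,
                   config$dense_units, config$n_classes),
       bo = rep(0, config$n_classes))
}

#' Build an untrained network
#'
#' @param feature_width number of input features per window (> 0).
#' @param config a \code{\link{model_config}}.
#' @return object of class \code{fall_lstm_net} with Glorot-initialized
#'   weights (forget-gate biases at 1), untrained.
#' @export
build_fall_lstm <- function(feature_width, config = model_config()) {
  stopifnot(feature_width > 0)
  weights <- with_preserved_seed(config$seed,
                                 .init_weights(feature_width, config))
  structure(list(weights = weights, config = config,
                 feature_width = as.integer(feature_width),
                 trained = FALSE, history = NULL),
            class = "fall_lstm_net")
}

#' Layer unit counts of a network
#'
#' @param net a \code{fall_lstm_net} or fitted \code{fall_lstm}.
#' @return integer vector: LSTM units, dense units, output units.
#' @export
layer_units <- function(net) {
  if (inherits(net, "fall_lstm")) net <- net$net
  c(net$config$lstm_units, net$config$dense_units, net$config$n_classes)
}

#' Rectified linear unit
#'
#' @param x numeric vector. @return \code{max(0, x)} elementwise.
#' @export
relu <- function(x) pmax(0, x)

#' Build training sequences from a feature matrix
#'
#' Sliding runs of \code{sequence_length} consecutive windows within
#' each trial (sequences never span trial boundaries); the sequence
#' label is the label of its final window. Trials shorter than one
#' sequence contribute nothing.
#'
#' @param features a \code{feature_matrix} (possibly stacked over
#'   trials).
#' @param sequence_length windows per sequence.
#' @param stride step between sequence starts within a trial.
#' @return list with \code{x} (array, dim \code{c(features, time,
#'   sequences)}), \code{label}, \code{activity}, \code{subject},
#'   \code{trial} (all per sequence).
#' @export
make_sequences <- function(features, sequence_length = 10, stride = 1) {
  stopifnot(inherits(features, "feature_matrix"),
            sequence_length >= 1, stride >= 1)
  Tn <- sequence_length
  Fw <- ncol(features$x)
  runs <- split(seq_len(nrow(features$x)), factor(features$trial,
                levels = unique(features$trial)))
  starts_per_run <- lapply(runs, function(rows) {
    if (length(rows) < Tn) integer(0)
    else rows[seq(1L, length(rows) - Tn + 1L, by = stride)]
  })
  n_seq <- sum(lengths(starts_per_run))
  x <- array(0, dim = c(Fw, Tn, n_seq))
  label <- integer(n_seq); activity <- character(n_seq)
  subject <- integer(n_seq); trial <- character(n_seq)
  k <- 0L
  for (starts in starts_per_run) {
    for (s in starts) {
      k <- k + 1L
      idx <- s:(s + Tn - 1L)
      x[, , k] <- t(features$x[idx, , drop = FALSE])
      fin <- idx[Tn]
      label[k] <- features$label[fin]
      activity[k] <- features$activity[fin]
      subject[k] <- features$subject[fin]
      trial[k] <- features$trial[fin]
    }
  }
  list(x = x, label = label, activity = activity,
       subject = subject, trial = trial)
}

.resolve_class_weights <- function(config, y) {
  if (is.numeric(config$class_weights)) {
    stopifnot(length(config$class_weights) == config$n_classes)
    return(as.numeric(config$class_weights))
  }
  counts <- tabulate(y + 1L, nbins = config$n_classes)
  if (any(counts == 0)) stop("training data contains a single class")
  length(y) / (config$n_classes * counts)
}

#' Train a network on prepared sequences
#'
#' Runs Adam over shuffled minibatches; all randomness (shuffling)
#' derives from \code{config$seed}, so two identical calls produce
#' identical histories and weights.
#'
#' @param net an (untrained or trained) \code{fall_lstm_net}.
#' @param x sequence array, dim \code{c(features, time, sequences)}.
#' @param y integer labels (0 = non-fall, 1 = fall).
#' @return the network with updated weights, \code{trained = TRUE} and
#'   a \code{history} data frame (epoch, loss, accuracy).
#' @export
train_fall_lstm <- function(net, x, y) {
  stopifnot(inherits(net, "fall_lstm_net"), length(dim(x)) == 3)
  if (dim(x)[1] != net$feature_width) {
    stop("sequence width ", dim(x)[1], " does not match model feature width ",
         net$feature_width)
  }
  cfg <- net$config
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training data contains a single class")
  cw <- .resolve_class_weights(cfg, y)
  n <- dim(x)[3]
  order <- with_preserved_seed(cfg$seed + 1L, {
    t(vapply(seq_len(cfg$epochs), function(e) sample.int(n),
             integer(n)))
  })
  fit <- cpp_lstm_train(net$weights, x, y, cw, cfg$learning_rate,
                        cfg$batch_size, cfg$epochs, order)
  net$weights <- fit$weights
  net$trained <- TRUE
  net$history <- data.frame(epoch = seq_len(cfg$epochs),
                            loss = fit$loss, accuracy = fit$accuracy)
  net
}

#' @export
predict.fall_lstm_net <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[1] != object$feature_width) {
    stop("sequence width ", dim(x)[1],
         " does not match model feature width ", object$feature_width)
  }
  probs <- cpp_lstm_predict(object$weights, x)
  colnames(probs) <- c("non_fall", "fall")
  if (type == "class") as.integer(probs[, 2] > 0.5) else probs
}

#' @export
print.fall_lstm_net <- function(x, ...) {
  cat(sprintf("<fall_lstm_net> %s, input width %d, %s\n",
              paste(layer_units(x), collapse = "-"), x$feature_width,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- high-level fitted detector ---------------------------------------

# stratified trial-level split: per activity, round(frac * n) trials train
.split_trials <- function(trial, activity, train_fraction, seed) {
  tr <- !duplicated(trial)
  trials <- trial[tr]; acts <- activity[tr]
  with_preserved_seed(seed, {
    train <- unlist(lapply(split(trials, acts), function(tt) {
      n_train <- max(1L, min(length(tt) - 1L,
                             round(train_fraction * length(tt))))
      sample(tt, n_train)
    }), use.names = FALSE)
    list(train = sort(train), test = sort(setdiff(trials, train)))
  })
}

.subset_sequences <- function(seqs, keep) {
  list(x = seqs$x[, , keep, drop = FALSE], label = seqs$label[keep],
       activity = seqs$activity[keep], subject = seqs$subject[keep],
       trial = seqs$trial[keep])
}

#' Fit the fall detector on a windowed feature matrix
#'
#' The full training pipeline: stratified trial-level 80/20 split (so
#' no window of a test trial ever leaks into training), optional
#' z-scoring fitted on the training split, sequence construction,
#' inverse-frequency class weighting, Adam training, and held-out
#' evaluation at the 0.5 probability threshold.
#'
#' @param features a stacked \code{feature_matrix} covering many
#'   trials.
#' @param config a \code{\link{model_config}}.
#' @param combination optional placement combination code; restricts
#'   the features to those nodes before fitting.
#' @return object of class \code{fall_lstm}: the trained network, the
#'   preprocessing state, the trial split, training history and
#'   held-out predictions.
#' @export
fall_lstm <- function(features, config = model_config(),
                      combination = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!is.null(combination)) features <- select_combination(features, combination)
  split <- .split_trials(features$trial, features$activity,
                         config$train_fraction, config$seed)

  center <- scale_ <- NULL
  if (isTRUE(config$standardize)) {
    rows <- features$trial %in% split$train
    center <- colMeans(features$x[rows, , drop = FALSE])
    scale_ <- pmax(apply(features$x[rows, , drop = FALSE], 2, sd), 1e-8)
    features$x <- sweep(sweep(features$x, 2, center), 2, scale_, "/")
  }

  seqs <- make_sequences(features, config$sequence_length,
                         config$sequence_stride)
  tr_idx <- which(seqs$trial %in% split$train)
  te_idx <- which(seqs$trial %in% split$test)
  if (is.finite(config$max_train_sequences) &&
      length(tr_idx) > config$max_train_sequences) {
    tr_idx <- with_preserved_seed(config$seed + 2L, {
      keep_frac <- config$max_train_sequences / length(tr_idx)
      keep <- unlist(lapply(split(tr_idx, seqs$label[tr_idx]), function(ii) {
        sample(ii, max(1L, round(keep_frac * length(ii))))
      }), use.names = FALSE)
      sort(keep)
    })
  }
  train_seq <- .subset_sequences(seqs, tr_idx)
  test_seq <- .subset_sequences(seqs, te_idx)

  net <- build_fall_lstm(ncol(features$x), config)
  net <- train_fall_lstm(net, train_seq$x, train_seq$label)

  test_prob <- if (length(te_idx)) predict(net, test_seq$x)[, "fall"] else numeric(0)
  structure(list(net = net, config = config, combination = combination,
                 center = center, scale = scale_, split = split,
                 history = net$history,
                 n_train = length(tr_idx), n_test = length(te_idx),
                 test = list(prob = test_prob, label = test_seq$label,
                             activity = test_seq$activity,
                             trial = test_seq$trial)),
            class = "fall_lstm")
}

#' @export
predict.fall_lstm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) {
    if (!is.null(object$combination)) {
      newdata <- select_combination(newdata, object$combination)
    }
    if (!is.null(object$center)) {
      newdata$x <- sweep(sweep(newdata$x, 2, object$center), 2,
                         object$scale, "/")
    }
    seqs <- make_sequences(newdata, object$config$sequence_length, 1L)
    x <- seqs$x
  } else {
    x <- newdata
  }
  p <- predict(object$net, x)
  if (type == "class") as.integer(p[, "fall"] > 0.5) else p[, "fall"]
}

#' @export
coef.fall_lstm <- function(object, ...) object$net$weights

#' @export
print.fall_lstm <- function(x, ...) {
  cat(sprintf("<fall_lstm> %s%s, %d train / %d test sequences\n",
              paste(layer_units(x), collapse = "-"),
              if (is.null(x$combination)) "" else paste0(" [", x$combination, "]"),
              x$n_train, x$n_test))
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              tail(x$history$loss, 1), tail(x$history$accuracy, 1)))
  invisible(x)
}

#' @export
summary.fall_lstm <- function(object, ...) {
  rep <- evaluate_detector(object)
  cat(sprintf("Fall detector (%s), held-out performance:\n",
              if (is.null(object$combination)) "CEWTA"
              else object$combination))
  cat(sprintf("  Se %.4f  Sp %.4f  Ac %.4f  AUC %.4f  (n = %d sequences)\n",
              rep$overall["se"], rep$overall["sp"], rep$overall["ac"],
              rep$overall["auc"], length(object$test$label)))
  invisible(rep)
}

#' @export
plot.fall_lstm <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Save / load a fitted detector
#'
#' Single-file persistence; a load-back predicts bit-identically.
#'
#' @param model a \code{fall_lstm} or \code{fall_lstm_net}.
#' @param path file path.
#' @return \code{read_fall_lstm} returns the restored object.
#' @export
save_fall_lstm <- function(model, path) {
  stopifnot(inherits(model, c("fall_lstm", "fall_lstm_net")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_fall_lstm
#' @export
read_fall_lstm <- function(path) readRDS(path)
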