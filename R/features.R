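# Windowed statistical features: each node contributes 13 channels
# (accel 3, gyro 3, quaternion 4, Euler 3); every window yields 4
# statistics per channel -- mean, range, population standard deviation
# and mean absolute deviation -- i.e. 52 features per physical IMU.

.CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz",
               "qw", "qx", "qy", "qz", "roll", "pitch", "yaw")
.STATS <- c("mu", "range", "sd", "mad")

#' Sliding-window index ranges
#'
#' Windows of \code{round(window_s * sample_rate)} samples advanced by
#' \code{max(1, round(hop_s * sample_rate))} samples, fully inside the
#' stream. At the default 0.5 s window / 0.1 s hop and 15 Hz this gives
#' 8-sample windows hopped by 2. A stream shorter than one window
#' yields zero windows.
#'
#' @param n_samples stream length.
#' @param window_s window length, seconds.
#' @param hop_s hop (stride), seconds.
#' @param sample_rate sampling rate, Hz.
#' @return integer matrix with columns \code{start}, \code{end}
#'   (1-based, inclusive), one row per window.
#' @export
window_indices <- function(n_samples, window_s = 0.5, hop_s = 0.1,
                           sample_rate = 15) {
  win <- as.integer(round(window_s * sample_rate))
  hop <- max(1L, as.integer(round(hop_s * sample_rate)))
  stopifnot(win >= 1)
  if (n_samples < win) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  n_win <- (n_samples - win) %/% hop + 1L
  start <- (seq_len(n_win) - 1L) * hop + 1L
  cbind(start = start, end = start + win - 1L)
}

#' The four window statistics
#'
#' For a window \code{x} of N samples: mean \eqn{\mu = \frac{1}{N}\sum
#' x_k}; range \eqn{R = \max x - \min x}; population standard deviation
#' \eqn{\sigma = \sqrt{\frac{1}{N}\sum (x_k-\mu)^2}} (1/N
#' normalization); mean absolute deviation \eqn{MAD = \frac{1}{N}\sum
#' |x_k - \mu|}.
#'
#' @param x numeric vector, length >= 1.
#' @return named numeric vector \code{c(mu, range, sd, mad)}.
#' @export
window_statistics <- function(x) {
  n <- length(x)
  if (n < 1) stop("empty window")
  mu <- sum(x) / n
  c(mu = mu,
    range = max(x) - min(x),
    sd = sqrt(sum((x - mu)^2) / n),
    mad = sum(abs(x - mu)) / n)
}

# all four statistics for every column of X over a set of windows;
# returns n_win x (4 * ncol(X)) with columns ordered (channel, stat).
# windows all share one length, so stats vectorize over windows.
.window_stats_matrix <- function(X, wins) {
  n_win <- nrow(wins)
  nc <- ncol(X)
  out <- matrix(0, n_win, 4L * nc)
  if (n_win == 0) return(out)
  win_len <- wins[1, 2] - wins[1, 1] + 1L
  idx <- outer(wins[, 1], 0:(win_len - 1L), "+")
  for (j in seq_len(nc)) {
    M <- matrix(X[, j][idx], n_win, win_len)
    mu <- rowMeans(M)
    mx <- M[, 1]; mn <- M[, 1]
    for (k in 2:win_len) {
      mx <- pmax(mx, M[, k]); mn <- pmin(mn, M[, k])
    }
    dev <- M - mu
    out[, (j - 1L) * 4L + 1:4] <- cbind(mu, mx - mn,
                                        sqrt(rowMeans(dev * dev)),
                                        rowMeans(abs(dev)))
  }
  out
}

#' Extract a windowed feature matrix from a recording
#'
#' Concatenates, for every window and every included node, the 13
#' per-sample channels x 4 statistics in (node, channel, statistic)
#' order with the statistic order (mu, range, sd, mad) — 52 features
#' per physical IMU, 468 for all nine. A window is labeled fall (1) iff
#' any sample inside it carries a fall label.
#'
#' @param recording a calibrated \code{fall_recording}.
#' @param orientations per-node orientation series from
#'   \code{\link{orient_recording}}, aligned sample-wise.
#' @param nodes node ids to include (default: all nine).
#' @param window_s,hop_s window length and hop, seconds.
#' @param label_rule \code{"any"} (default: any fall sample labels the
#'   window) or \code{"majority"}.
#' @return object of class \code{feature_matrix}: list with \code{x}
#'   (n_windows x width matrix with named columns
#'   \code{<node>_<channel>_<stat>}), \code{label}, \code{activity},
#'   \code{subject}, \code{trial}, \code{windows}.
#' @export
extract_features <- function(recording, orientations,
                             nodes = node_ids(),
                             window_s = 0.5, hop_s = 0.1,
                             label_rule = c("any", "majority")) {
  stopifnot(inherits(recording, "fall_recording"))
  label_rule <- match.arg(label_rule)
  if (length(nodes) == 0) stop("node set is empty")
  missing_nodes <- setdiff(nodes, names(recording$streams))
  if (length(missing_nodes)) {
    stop("recording lacks node(s): ", paste(missing_nodes, collapse = ", "))
  }
  n <- length(recording$t)
  wins <- window_indices(n, window_s, hop_s, recording$sample_rate)
  n_win <- nrow(wins)

  blocks <- vector("list", length(nodes))
  for (j in seq_along(nodes)) {
    nd <- nodes[j]
    ori <- orientations[[nd]]
    if (is.null(ori) || nrow(ori$q) != n) {
      stop("orientation series misaligned for node ", nd)
    }
    chan <- cbind(recording$streams[[nd]]$accel,
                  recording$streams[[nd]]$gyro,
                  ori$q, ori$euler)
    blocks[[j]] <- .window_stats_matrix(chan, wins)
  }
  x <- do.call(cbind, blocks)
  colnames(x) <- as.vector(t(outer(nodes, as.vector(t(outer(.CHANNELS, .STATS,
                   FUN = paste, sep = "_"))), FUN = paste, sep = "_")))

  lab <- integer(n_win)
  if (n_win > 0) {
    for (w in seq_len(n_win)) {
      seg <- recording$labels[wins[w, 1]:wins[w, 2]]
      lab[w] <- if (label_rule == "any") as.integer(any(seg == 1L))
                else as.integer(mean(seg) > 0.5)
    }
  }
  structure(list(
    x = x, label = lab,
    activity = rep(recording$activity, n_win),
    subject = rep(recording$subject$subject_id, n_win),
    trial = rep(trial_id(recording), n_win),
    windows = wins),
    class = "feature_matrix")
}

# unique trial identifier string
trial_id <- function(recording) {
  sprintf("s%02d_%s_t%02d", recording$subject$subject_id,
          recording$activity, recording$trial_index)
}

#' Combine feature matrices from several trials
#'
#' @param feature_list list of \code{feature_matrix} objects with
#'   identical column layouts.
#' @return one stacked \code{feature_matrix}.
#' @export
bind_features <- function(feature_list) {
  stopifnot(length(feature_list) > 0)
  widths <- vapply(feature_list, function(f) ncol(f$x), integer(1))
  if (length(unique(widths)) != 1) stop("feature widths differ across trials")
  structure(list(
    x = do.call(rbind, lapply(feature_list, `[[`, "x")),
    label = unlist(lapply(feature_list, `[[`, "label"), use.names = FALSE),
    activity = unlist(lapply(feature_list, `[[`, "activity"), use.names = FALSE),
    subject = unlist(lapply(feature_list, `[[`, "subject"), use.names = FALSE),
    trial = unlist(lapply(feature_list, `[[`, "trial"), use.names = FALSE),
    windows = do.call(rbind, lapply(feature_list, `[[`, "windows"))),
    class = "feature_matrix")
}

#' Restrict a feature matrix to a sensor combination
#'
#' @param features a \code{feature_matrix}.
#' @param code placement combination code (see
#'   \code{\link{combination_nodes}}).
#' @return \code{feature_matrix} with only that combination's columns.
#' @export
select_combination <- function(features, code) {
  nodes <- combination_nodes(code)
  keep <- unlist(lapply(nodes, function(nd) {
    grep(paste0("^", nd, "_"), colnames(features$x))
  }))
  out <- features
  out$x <- features$x[, keep, drop = FALSE]
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d fall-labeled)\n",
              nrow(x$x), ncol(x$x), sum(x$label)))
  invisible(x)
}
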