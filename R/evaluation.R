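# Evaluation: sensitivity / specificity / accuracy, ROC/AUC,
# per-activity breakdowns and the sensor-placement ablation.

#' Confusion counts at a decision threshold
#'
#' @param scores predicted fall probabilities.
#' @param labels binary truth (1 = fall).
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector \code{c(tp, tn, fp, fn)}.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores > threshold)
  c(tp = sum(pred == 1 & labels == 1),
    tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Se = TP/(TP+FN), Sp = TN/(TN+FP), Ac = (TP+TN)/total. When a subset
#' contains no true falls (TP+FN = 0, e.g. fall-like activities), Se is
#' reported as 0 by convention; likewise Sp when there are no true
#' negatives.
#'
#' @param counts named vector with \code{tp}, \code{tn}, \code{fp},
#'   \code{fn} (all >= 0, total > 0).
#' @return named numeric vector \code{c(se, sp, ac)}.
#' @export
classification_metrics <- function(counts) {
  counts <- counts[c("tp", "tn", "fp", "fn")]
  stopifnot(all(!is.na(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("no predictions to score")
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  c(se = if (tp + fn > 0) tp / (tp + fn) else 0,
    sp = if (tn + fp > 0) tn / (tn + fp) else 0,
    ac = (tp + tn) / total)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (ties cross
#' together) and integrates the curve by the trapezoidal rule.
#'
#' @param scores predicted fall probabilities (or any monotone score).
#' @param labels binary truth; both classes must be present.
#' @return list with \code{points} (data frame \code{fpr}, \code{tpr},
#'   monotone non-decreasing) and \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE)   # collapse score ties
  tpr <- c(0, tp[last] / n_pos); fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Held-out evaluation report for a fitted detector
#'
#' @param model a fitted \code{\link{fall_lstm}}.
#' @param threshold decision threshold for the confusion counts.
#' @return object of class \code{fall_eval}: overall Se/Sp/Ac/AUC,
#'   per-activity table, ROC points, confusion counts and the
#'   combination code.
#' @export
evaluate_detector <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "fall_lstm"))
  scores <- model$test$prob; labels <- model$test$label
  if (!length(scores)) stop("model holds no held-out predictions")
  counts <- confusion_counts(scores, labels, threshold)
  m <- classification_metrics(counts)
  roc <- roc_curve(scores, labels)
  structure(list(
    overall = c(m, auc = roc$auc),
    counts = counts,
    per_activity = per_activity_report(scores, model$test$activity,
                                       labels, threshold),
    roc_points = roc$points,
    combination = if (is.null(model$combination)) "CEWTA"
                  else model$combination),
    class = "fall_eval")
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(sprintf("<fall_eval> [%s]  Se %.4f  Sp %.4f  Ac %.4f  AUC %.4f\n",
              x$combination, x$overall["se"], x$overall["sp"],
              x$overall["ac"], x$overall["auc"]))
  print(x$per_activity, digits = 4)
  invisible(x)
}

#' Per-activity detection efficiency
#'
#' Metrics on the subset of predictions drawn from each activity.
#' Fall-like activities contain no true falls, so their Se is 0 by
#' convention and Sp equals Ac. Activities absent from the predictions
#' are omitted with a warning.
#'
#' @param predictions fall probabilities.
#' @param window_activities activity code of each prediction's source
#'   window.
#' @param labels binary truth.
#' @param threshold decision threshold.
#' @return data frame with rows per activity: se, sp, ac, n.
#' @export
per_activity_report <- function(predictions, window_activities, labels,
                                threshold = 0.5) {
  stopifnot(length(predictions) == length(window_activities),
            length(predictions) == length(labels))
  bad <- setdiff(unique(window_activities), activity_codes())
  if (length(bad)) stop("unknown activity code(s): ", paste(bad, collapse = ", "))
  acts <- intersect(activity_codes(), unique(window_activities))
  absent <- setdiff(activity_codes(), acts)
  if (length(absent)) {
    warning("no predictions for activity(ies): ",
            paste(absent, collapse = ", "), "; row(s) omitted")
  }
  rows <- lapply(acts, function(a) {
    sel <- window_activities == a
    m <- classification_metrics(confusion_counts(predictions[sel],
                                                 labels[sel], threshold))
    data.frame(activity = a, se = m[["se"]], sp = m[["sp"]], ac = m[["ac"]],
               n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Sensor-placement ablation
#'
#' Trains and evaluates one model per placement combination on the
#' same trial-level split and seed (differences between rows therefore
#' reflect the sensor sets, not resampling). The default list is the 30
#' standard combinations.
#'
#' @param features a stacked \code{feature_matrix} over all nine nodes.
#' @param combinations character vector of combination codes.
#' @param config a \code{\link{model_config}} shared by all runs.
#' @return data frame with one row per combination: code, imu_quantity,
#'   feature width, auc, se, sp, ac; the fitted models are attached as
#'   the \code{"models"} attribute.
#' @export
run_ablation <- function(features, combinations = ablation_combinations(),
                         config = model_config()) {
  stopifnot(inherits(features, "feature_matrix"))
  lapply(combinations, validate_combination)
  models <- vector("list", length(combinations))
  rows <- vector("list", length(combinations))
  for (i in seq_along(combinations)) {
    code <- combinations[i]
    fit <- fall_lstm(features, config, combination = code)
    rep <- evaluate_detector(fit)
    models[[i]] <- fit
    rows[[i]] <- data.frame(
      combination = code,
      imu_quantity = imu_quantity(code),
      feature_width = fit$net$feature_width,
      auc = rep$overall[["auc"]],
      se = rep$overall[["se"]],
      sp = rep$overall[["sp"]],
      ac = rep$overall[["ac"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}
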