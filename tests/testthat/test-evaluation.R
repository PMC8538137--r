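test_that("classification metrics equal their defining ratios", {
  m <- classification_metrics(c(tp = 9, fn = 1, tn = 18, fp = 2))
  expect_equal(unname(m), c(0.90, 0.90, 0.90))
  expect_equal(unname(classification_metrics(c(tp = 5, tn = 5, fp = 0, fn = 0))),
               c(1, 1, 1))
  # no true falls in the subset: Se reported as 0 by convention
  m0 <- classification_metrics(c(tp = 0, fn = 0, tn = 7, fp = 3))
  expect_equal(m0[["se"]], 0)
  expect_equal(m0[["sp"]], 0.7)
  expect_equal(m0[["ac"]], 0.7)
  expect_error(classification_metrics(c(tp = 0, tn = 0, fp = 0, fn = 0)))
})

test_that("metrics agree with direct counting on random confusion tables", {
  set.seed(19)
  for (i in 1:100) {
    n <- 60
    labels <- sample(0:1, n, TRUE)
    scores <- runif(n)
    counts <- confusion_counts(scores, labels)
    pred <- as.integer(scores > 0.5)
    expect_equal(counts[["tp"]], sum(pred & labels))
    expect_equal(counts[["tn"]], sum(!pred & !labels))
    expect_equal(sum(counts), n)
    if (sum(labels) %in% c(0, n)) next
    m <- classification_metrics(counts)
    # accuracy is a prevalence-weighted mean of Se and Sp
    expect_gte(m[["ac"]], min(m[["se"]], m[["sp"]]) - 1e-12)
    expect_lte(m[["ac"]], max(m[["se"]], m[["sp"]]) + 1e-12)
  }
})

test_that("ROC endpoints and degenerate score sets behave canonically", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)
  flat <- roc_curve(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
  # curve is monotone non-decreasing in both coordinates
  set.seed(3)
  r <- roc_curve(runif(40), sample(0:1, 40, TRUE))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ], use.names = FALSE), c(1, 1))
})

test_that("AUC equals the Mann-Whitney pairwise estimate", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)   # rounding forces ties
    auc <- roc_curve(scores, labels)$auc
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(37)
  scores <- runif(30); labels <- c(0, 1, sample(0:1, 28, TRUE))
  a1 <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(plogis(5 * scores - 2), labels)$auc, a1)
  expect_equal(roc_curve(scores^3, labels)$auc, a1)
})

test_that("AUC matches pROC on a random sample", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- runif(50); labels <- c(0, 1, sample(0:1, 48, TRUE))
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("per-activity rows split the predictions correctly", {
  acts <- rep(c("F1", "FL2"), each = 10)
  labels <- c(rep(1, 6), rep(0, 4), rep(0, 10))
  scores <- c(rep(0.9, 5), 0.1, rep(0.05, 4), rep(0.2, 8), 0.8, 0.9)
  tab <- suppressWarnings(per_activity_report(scores, acts, labels))
  f1 <- tab[tab$activity == "F1", ]
  expect_equal(f1$se, 5 / 6)
  expect_equal(f1$sp, 1)
  fl2 <- tab[tab$activity == "FL2", ]
  expect_equal(fl2$se, 0)         # no true falls in a fall-like activity
  expect_equal(fl2$sp, fl2$ac)    # forced by TP = FN = 0
  expect_equal(fl2$sp, 0.8)
  expect_warning(per_activity_report(scores, acts, labels), "omitted")
  expect_error(per_activity_report(scores, rep("XX", 20), labels),
               "unknown activity")
})

test_that("the ablation runner trains one model per combination on a shared split", {
  feats <- tiny_features()
  cfg <- model_config(lstm_units = c(6, 4), dense_units = 4, epochs = 4,
                      sequence_length = 8, seed = 7)
  tab <- run_ablation(feats, c("C", "CA", "CEW"), cfg)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$feature_width, c(52, 156, 260))
  expect_equal(tab$imu_quantity, c(1, 3, 5))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$ac >= 0 & tab$ac <= 1))
  models <- attr(tab, "models")
  expect_equal(models[[1]]$split, models[[3]]$split)
  expect_error(run_ablation(feats, c("C", "XY"), cfg), "invalid placement")
})
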