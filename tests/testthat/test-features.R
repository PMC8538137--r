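test_that("window enumeration matches explicit index arithmetic", {
  w <- window_indices(20, window_s = 8 / 15, hop_s = 2 / 15, sample_rate = 15)
  expect_equal(nrow(w), 7)
  expect_equal(w[, "start"], seq(1, 13, by = 2))
  expect_equal(w[, "end"], seq(8, 20, by = 2))
  # too short: zero windows, not an error
  expect_equal(nrow(window_indices(7, 8 / 15, 2 / 15, 15)), 0)
  # the defaults at 15 Hz round 7.5 samples up to 8 and 1.5 to 2
  w15 <- window_indices(120)
  expect_equal(w15[1, ], c(start = 1, end = 8))
  expect_equal(unname(w15[2, "start"] - w15[1, "start"]), 2)
  expect_equal(nrow(w15), (120 - 8) %/% 2 + 1)
})

test_that("window statistics equal their defining formulas", {
  expect_equal(window_statistics(rep(3.7, 9)),
               c(mu = 3.7, range = 0, sd = 0, mad = 0))
  s <- window_statistics(c(1, 2, 3, 4))
  expect_equal(s[["mu"]], 2.5)
  expect_equal(s[["range"]], 3)
  expect_equal(s[["sd"]], sqrt(1.25))
  expect_equal(s[["mad"]], 1.0)
  expect_error(window_statistics(numeric(0)), "empty")
})

test_that("statistics agree with brute-force evaluation on random vectors", {
  set.seed(13)
  for (i in 1:200) {
    x <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 10))
    s <- window_statistics(x)
    n <- length(x)
    mu <- sum(x) / n
    expect_equal(s[["mu"]], mu, tolerance = 1e-12)
    expect_equal(s[["range"]], max(x) - min(x), tolerance = 1e-12)
    expect_equal(s[["sd"]], sqrt(sum((x - mu)^2) / n), tolerance = 1e-12)
    expect_equal(s[["mad"]], sum(abs(x - mu)) / n, tolerance = 1e-12)
    # mean absolute deviation never exceeds the standard deviation
    expect_lte(s[["mad"]], s[["sd"]] + 1e-12)
  }
})

test_that("feature width is 52 per physical IMU", {
  rec <- simulate_recording("F1", subject_params(1, 1.74), heading = 5,
                            seed = 77, duration = 5)
  cal <- apply_calibration(rec, calibrate_recording(rec))
  ori <- orient_recording(cal)
  all9 <- extract_features(cal, ori)
  expect_equal(ncol(all9$x), 468)
  five <- extract_features(cal, ori, nodes = combination_nodes("CEW"))
  expect_equal(ncol(five$x), 260)
  one <- extract_features(cal, ori, nodes = "chest")
  expect_equal(ncol(one$x), 52)
  expect_error(extract_features(cal, ori, nodes = character(0)), "empty")
  expect_error(extract_features(cal, ori, nodes = "hip"), "lacks node")
  # column naming carries (node, channel, stat) order
  expect_equal(colnames(all9$x)[1:4],
               c("chest_ax_mu", "chest_ax_range", "chest_ax_sd", "chest_ax_mad"))
  expect_equal(colnames(one$x)[49:52],
               c("chest_yaw_mu", "chest_yaw_range", "chest_yaw_sd",
                 "chest_yaw_mad"))
})

test_that("adding a constant shifts only the mean features", {
  rec <- simulate_recording("F5", subject_params(1, 1.8), heading = 90,
                            seed = 31, duration = 5)
  cal <- apply_calibration(rec, calibrate_recording(rec))
  ori <- orient_recording(cal)
  f0 <- extract_features(cal, ori, nodes = "chest")
  cal2 <- cal
  cal2$streams$chest$accel <- cal2$streams$chest$accel + 5
  f1 <- extract_features(cal2, ori, nodes = "chest")
  mu_cols <- grep("_a[xyz]_mu$", colnames(f0$x))
  other_accel <- setdiff(grep("_a[xyz]_", colnames(f0$x)), mu_cols)
  expect_equal(f1$x[, mu_cols], f0$x[, mu_cols] + 5, tolerance = 1e-9)
  expect_equal(f1$x[, other_accel], f0$x[, other_accel], tolerance = 1e-12)
})

test_that("window labels follow the any-fall-sample rule", {
  rec <- simulate_recording("F2", subject_params(1, 1.78), heading = 0,
                            seed = 41)
  cal <- apply_calibration(rec, calibrate_recording(rec))
  ori <- orient_recording(cal)
  f <- extract_features(cal, ori, nodes = "chest")
  expect_gt(sum(f$label), 0)
  # oracle: recompute labels from the per-sample labels and window spans
  manual <- apply(f$windows, 1, function(w) {
    as.integer(any(rec$labels[w[1]:w[2]] == 1L))
  })
  expect_equal(f$label, manual)
  # fall-like trials produce no positive windows
  rec2 <- simulate_recording("FL2", subject_params(1, 1.78), heading = 0,
                             seed = 42)
  cal2 <- apply_calibration(rec2, calibrate_recording(rec2))
  f2 <- extract_features(cal2, orient_recording(cal2), nodes = "chest")
  expect_equal(sum(f2$label), 0)
})

test_that("all-zero channels give all-zero statistics", {
  X <- matrix(0, 30, 2)
  wins <- window_indices(30, sample_rate = 15)
  out <- imufall:::.window_stats_matrix(X, wins)
  expect_true(all(out == 0))
})

test_that("feature matrices stack and subset consistently", {
  feats <- tiny_features()
  expect_equal(ncol(feats$x), 468)
  expect_equal(length(feats$label), nrow(feats$x))
  sub <- select_combination(feats, "CA")
  expect_equal(ncol(sub$x), 3 * 52)
  expect_true(all(grepl("^(chest|ankle_l|ankle_r)_", colnames(sub$x))))
  expect_error(bind_features(list()))
})
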