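make_static_stream <- function(accel, mag, n = 20, gyro = c(0, 0, 0)) {
  list(accel = matrix(accel, n, 3, byrow = TRUE),
       gyro = matrix(gyro, n, 3, byrow = TRUE),
       mag = matrix(mag, n, 3, byrow = TRUE))
}

test_that("reference vectors are the mean of exactly the first 15 samples", {
  st <- make_static_stream(c(0, 0, 9.81), c(30, 0, -40), n = 15)
  ref <- estimate_reference_vectors(st)
  expect_equal(unname(ref$v_acc), c(0, 0, 9.81))
  expect_equal(unname(ref$v_mag), c(30, 0, -40))

  # samples 16-20 differ wildly; result must not change
  st2 <- make_static_stream(c(0, 0, 9.81), c(30, 0, -40), n = 20)
  st2$accel[16:20, ] <- 1000
  st2$mag[16:20, ] <- -1000
  ref2 <- estimate_reference_vectors(st2)
  expect_equal(ref2, ref)
})

test_that("reference vector noise shrinks as the CLT predicts", {
  set.seed(31)
  ok <- 0
  for (rep in 1:20) {
    st <- make_static_stream(c(0, 0, 9.81), c(30, 0, -40), n = 15)
    st$accel <- st$accel + matrix(rnorm(45, 0, 0.1), 15, 3)
    ref <- estimate_reference_vectors(st)
    if (all(abs(ref$v_acc - c(0, 0, 9.81)) <= 3 * 0.1 / sqrt(15))) ok <- ok + 1
  }
  expect_gte(ok, 18)  # per-axis 3-sigma bound holds in nearly all replicates
})

test_that("calibration refuses non-static prefixes and short streams", {
  st <- make_static_stream(c(0, 0, 9.81), c(30, 0, -40), n = 10)
  expect_error(estimate_reference_vectors(st), "too short")
  st2 <- make_static_stream(c(0, 0, 9.81), c(30, 0, -40), gyro = c(30, 0, 0))
  expect_error(estimate_reference_vectors(st2), "static check failed")
})

test_that("TRIAD construction matches explicit arithmetic", {
  expect_equal(unname(compute_neu_rotation(c(0, 0, 1), c(1, 0, 0))), diag(3),
               tolerance = 1e-12)
  R <- compute_neu_rotation(c(0, 0, 1), c(0, 1, 0))
  expect_equal(unname(R),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-12)
  # vertical magnetic component is discarded
  expect_equal(unname(compute_neu_rotation(c(0, 0, 1), c(1, 0, 1))), diag(3),
               tolerance = 1e-12)
  expect_error(compute_neu_rotation(c(0, 0, 0), c(1, 0, 0)), "zero")
  expect_error(compute_neu_rotation(c(0, 0, 1), c(0, 0, 2)), "parallel")
})

test_that("TRIAD rotations are orthonormal with determinant +1", {
  set.seed(17)
  for (i in 1:50) {
    R <- compute_neu_rotation(rnorm(3), rnorm(3))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("TRIAD recovers a known orientation exactly without noise, within 2 deg with noise", {
  set.seed(23)
  n_noisy_ok <- 0
  for (i in 1:100) {
    R_true <- quaternion_to_rotation(random_quat())
    acc_body <- as.numeric(t(R_true) %*% c(0, 0, 9.81))
    mag_body <- as.numeric(t(R_true) %*% c(30, 0, -40))
    R_hat <- compute_neu_rotation(acc_body, mag_body)
    expect_lt(norm(R_hat - R_true, "F"), 1e-10)
    # default noise on the 15-sample averages
    acc_n <- acc_body + colMeans(matrix(rnorm(45, 0, 0.15), 15, 3))
    mag_n <- mag_body + colMeans(matrix(rnorm(45, 0, 0.5), 15, 3))
    err <- imufall:::rotation_angle_deg(compute_neu_rotation(acc_n, mag_n),
                                        R_true)
    if (err < 2) n_noisy_ok <- n_noisy_ok + 1
  }
  expect_gte(n_noisy_ok, 95)
})

test_that("calibrated nodes share one magnetic frame", {
  rec <- simulate_recording("F1", subject_params(1, 1.76), heading = 310,
                            seed = 55)
  cal <- apply_calibration(rec, calibrate_recording(rec))
  prefix <- seq_len(15)
  mags <- sapply(node_ids(), function(nd) {
    colMeans(cal$streams[[nd]]$mag[prefix, ])
  })
  ref <- mags[, 1] / sqrt(sum(mags[, 1]^2))
  for (j in 2:ncol(mags)) {
    v <- mags[, j] / sqrt(sum(mags[, j]^2))
    ang <- acos(min(1, sum(v * ref))) * 180 / pi
    expect_lt(ang, 3)
  }
  # and gravity reads (0, 0, +9.81) everywhere
  for (nd in node_ids()) {
    expect_equal(unname(colMeans(cal$streams[[nd]]$accel[prefix, ])),
                 c(0, 0, 9.81), tolerance = 0.3)
  }
})

test_that("applying calibration preserves norms and rejects missing nodes", {
  rec <- simulate_recording("FL2", subject_params(1, 1.8), heading = 10,
                            seed = 6)
  params <- calibrate_recording(rec)
  cal <- apply_calibration(rec, params)
  for (nd in c("chest", "ankle_r")) {
    expect_equal(sqrt(rowSums(cal$streams[[nd]]$accel^2)),
                 sqrt(rowSums(rec$streams[[nd]]$accel^2)), tolerance = 1e-12)
    expect_equal(sqrt(rowSums(cal$streams[[nd]]$gyro^2)),
                 sqrt(rowSums(rec$streams[[nd]]$gyro^2)), tolerance = 1e-12)
  }
  expect_identical(cal$labels, rec$labels)
  expect_identical(cal$t, rec$t)
  # identity rotations leave the recording unchanged
  ident <- lapply(params, function(p) { p$r_neu <- diag(3); p })
  same <- apply_calibration(rec, ident)
  expect_equal(same$streams, rec$streams, tolerance = 1e-12)
  expect_error(apply_calibration(rec, params[-1]), "missing calibration")
})
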