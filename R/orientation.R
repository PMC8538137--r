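# Mahony attitude and heading reference system (AHRS): estimates each
# node's orientation quaternion by fusing gyroscope integration with a
# proportional-integral correction driven by the cross products between
# measured and quaternion-predicted gravity and magnetic directions.

#' Mahony filter gains
#'
#' @param kp proportional gain (unitless, >= 0). Default 1.0.
#' @param ki integral gain (unitless, >= 0). Default 0 (pure
#'   proportional), standard practice at low sample rates.
#' @return object of class \code{ahrs_gains}.
#' @export
ahrs_gains <- function(kp = 1.0, ki = 0.0) {
  stopifnot(kp >= 0, ki >= 0)
  structure(list(kp = kp, ki = ki), class = "ahrs_gains")
}

#' Initial orientation state
#'
#' @param q initial unit quaternion (w, x, y, z).
#' @return object of class \code{orientation_state} with the quaternion
#'   and the PI integral-error accumulator.
#' @export
orientation_state <- function(q = c(1, 0, 0, 0)) {
  structure(list(q = quat_normalize(q), integral_error = c(0, 0, 0)),
            class = "orientation_state")
}

#' One Mahony AHRS update
#'
#' Propagates the orientation quaternion over one sample: the angular
#' rate (converted to rad/s internally) is corrected by
#' \code{kp * e + ki * integral(e)}, where \code{e} is the sum of cross
#' products between the measured accelerometer/magnetometer directions
#' and the directions predicted from the current quaternion; the
#' quaternion is then integrated over \code{dt} and renormalized. If the
#' accelerometer or magnetometer sample is (near) zero, that reference
#' drops out and the update degrades gracefully toward gyro-only
#' integration.
#'
#' @param state an \code{\link{orientation_state}}.
#' @param gyro angular rate, deg/s (length 3).
#' @param accel specific force, m/s^2 (length 3).
#' @param mag magnetic field, uT (length 3).
#' @param dt sample interval, seconds (> 0).
#' @param gains an \code{\link{ahrs_gains}} object.
#' @return updated \code{orientation_state} (unit-norm quaternion).
#' @export
mahony_step <- function(state, gyro, accel, mag, dt,
                        gains = ahrs_gains()) {
  if (!all(is.finite(c(gyro, accel, mag, dt))) || dt <= 0) {
    stop("mahony_step requires finite inputs and dt > 0")
  }
  q <- state$q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  err <- c(0, 0, 0)

  an <- sqrt(sum(accel^2))
  if (an > 1e-9) {
    a <- accel / an
    # predicted world-up direction in the body frame (third row of R(q))
    v <- c(2 * (x * z - y * w), 2 * (y * z + x * w), 2 * (w^2 + z^2) - 1)
    err <- err + c(a[2] * v[3] - a[3] * v[2],
                   a[3] * v[1] - a[1] * v[3],
                   a[1] * v[2] - a[2] * v[1])
  }
  mn <- sqrt(sum(mag^2))
  if (mn > 1e-9) {
    m <- mag / mn
    R <- quaternion_to_rotation(q)
    h <- as.numeric(R %*% m)                       # measured field in world
    b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])          # reference: north + vertical
    wpred <- b[1] * R[1, ] + b[3] * R[3, ]          # R' %*% b
    err <- err + c(m[2] * wpred[3] - m[3] * wpred[2],
                   m[3] * wpred[1] - m[1] * wpred[3],
                   m[1] * wpred[2] - m[2] * wpred[1])
  }

  integ <- state$integral_error + err * dt * (gains$ki > 0)
  omega <- gyro * pi / 180 + gains$kp * err + gains$ki * integ
  dq <- 0.5 * quat_multiply(q, c(0, omega))
  structure(list(q = quat_normalize(q + dq * dt), integral_error = integ),
            class = "orientation_state")
}

#' Run the Mahony filter over a whole stream
#'
#' @param stream per-node stream (list with \code{accel}, \code{gyro},
#'   \code{mag} n x 3 matrices).
#' @param sample_rate sampling rate, Hz.
#' @param gains an \code{\link{ahrs_gains}} object.
#' @param init \code{"triad"} (default) starts from the two-vector
#'   attitude of the first \code{n_init} samples so the filter begins
#'   converged; \code{"identity"} starts from the identity quaternion.
#' @param n_init samples averaged for the TRIAD initialization.
#' @return list with \code{q} (n x 4 quaternion matrix) and
#'   \code{euler} (n x 3 roll/pitch/yaw, degrees).
#' @export
mahony_filter <- function(stream, sample_rate,
                          gains = ahrs_gains(),
                          init = c("triad", "identity"), n_init = 15) {
  init <- match.arg(init)
  n <- nrow(stream$accel)
  dt <- 1 / sample_rate
  q0 <- c(1, 0, 0, 0)
  if (init == "triad" && n >= n_init) {
    k <- seq_len(min(n_init, n))
    R0 <- try(compute_neu_rotation(colMeans(stream$accel[k, , drop = FALSE]),
                                   colMeans(stream$mag[k, , drop = FALSE])),
              silent = TRUE)
    if (!inherits(R0, "try-error")) q0 <- rotation_to_quaternion(R0)
  }
  state <- orientation_state(q0)
  Q <- matrix(0, n, 4)
  E <- matrix(0, n, 3, dimnames = list(NULL, c("roll", "pitch", "yaw")))
  for (i in seq_len(n)) {
    state <- mahony_step(state, stream$gyro[i, ], stream$accel[i, ],
                         stream$mag[i, ], dt, gains)
    Q[i, ] <- state$q
    E[i, ] <- quaternion_to_euler(state$q)
  }
  colnames(Q) <- c("qw", "qx", "qy", "qz")
  list(q = Q, euler = E)
}

#' Estimate orientations for every node of a recording
#'
#' @param recording a (typically calibrated) \code{fall_recording}.
#' @param gains,init,n_init passed to \code{\link{mahony_filter}}.
#' @return named list (one entry per node) of \code{mahony_filter}
#'   outputs, aligned sample-wise with the recording.
#' @export
orient_recording <- function(recording, gains = ahrs_gains(),
                             init = "triad", n_init = 15) {
  stopifnot(inherits(recording, "fall_recording"))
  lapply(recording$streams, mahony_filter, sample_rate = recording$sample_rate,
         gains = gains, init = init, n_init = n_init)
}
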