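# Global calibration: rotate every node's local frame into the shared
# north-east-up (NEU) earth frame using gravity and magnetic reference
# vectors averaged over the initial 1-second (15-sample) static stance.

#' Estimate static reference vectors for one node
#'
#' Averages the first \code{n_samples} accelerometer and magnetometer
#' samples of a stream (1 s at 15 Hz). The prefix must be quasi-static:
#' the mean gyroscope magnitude over those samples has to stay below
#' \code{static_gyro_max}; otherwise calibration refuses rather than
#' silently mis-calibrating.
#'
#' @param stream a per-node stream: list with \code{accel}, \code{gyro},
#'   \code{mag} matrices (n x 3).
#' @param n_samples number of leading samples to average (default 15).
#' @param static_gyro_max quasi-static gyro threshold, deg/s.
#' @return list with \code{v_acc} (m/s^2) and \code{v_mag} (uT).
#' @export
estimate_reference_vectors <- function(stream, n_samples = 15,
                                       static_gyro_max = 2) {
  stopifnot(is.list(stream), !is.null(stream$accel), !is.null(stream$mag))
  if (nrow(stream$accel) < n_samples) {
    stop("stream too short for calibration: ", nrow(stream$accel),
         " < ", n_samples, " samples")
  }
  idx <- seq_len(n_samples)
  gyro_mag <- sqrt(rowSums(stream$gyro[idx, , drop = FALSE]^2))
  if (mean(gyro_mag) > static_gyro_max) {
    stop("static check failed: mean |gyro| = ", signif(mean(gyro_mag), 4),
         " deg/s exceeds ", static_gyro_max,
         " deg/s during the calibration prefix")
  }
  list(v_acc = colMeans(stream$accel[idx, , drop = FALSE]),
       v_mag = colMeans(stream$mag[idx, , drop = FALSE]))
}

#' TRIAD rotation from local frame to NEU
#'
#' Deterministic two-vector attitude construction. The up axis is the
#' normalized static specific-force vector (a static accelerometer
#' reports +g along its body-frame up axis); north is the magnetic
#' reference with its vertical component removed; east completes the
#' right-handed frame (E = U x N). The returned matrix has rows N, E, U,
#' so \code{R \%*\% v_local} expresses a local vector in NEU
#' coordinates.
#'
#' @param v_acc static accelerometer mean, m/s^2.
#' @param v_mag static magnetometer mean, uT.
#' @return 3x3 rotation matrix (orthonormal, det +1).
#' @export
compute_neu_rotation <- function(v_acc, v_mag) {
  stopifnot(length(v_acc) == 3, length(v_mag) == 3)
  na <- sqrt(sum(v_acc^2))
  if (na < 1e-9) stop("degenerate calibration: zero acceleration vector")
  up <- v_acc / na
  horiz <- v_mag - sum(v_mag * up) * up
  nh <- sqrt(sum(horiz^2))
  if (nh < 1e-9 * max(1, sqrt(sum(v_mag^2)))) {
    stop("degenerate calibration: magnetic vector parallel to gravity")
  }
  north <- horiz / nh
  east <- c(up[2] * north[3] - up[3] * north[2],
            up[3] * north[1] - up[1] * north[3],
            up[1] * north[2] - up[2] * north[1])
  rbind(N = north, E = east, U = up)
}

#' Calibrate every node of a recording
#'
#' Estimates per-node reference vectors from the static prefix and the
#' TRIAD rotation into NEU, returning a named list of calibration
#' parameters (one per node).
#'
#' @param recording a \code{fall_recording}.
#' @param n_samples static samples to average (default 15).
#' @param static_gyro_max quasi-static gyro threshold, deg/s.
#' @return named list of per-node lists \code{(node_id, v_acc, v_mag,
#'   r_neu)}.
#' @export
calibrate_recording <- function(recording, n_samples = 15,
                                static_gyro_max = 2) {
  stopifnot(inherits(recording, "fall_recording"))
  out <- lapply(names(recording$streams), function(nd) {
    ref <- estimate_reference_vectors(recording$streams[[nd]], n_samples,
                                      static_gyro_max)
    list(node_id = nd, v_acc = ref$v_acc, v_mag = ref$v_mag,
         r_neu = compute_neu_rotation(ref$v_acc, ref$v_mag))
  })
  names(out) <- names(recording$streams)
  out
}

#' Apply calibration rotations to a recording
#'
#' Rotates every vector channel (accelerometer, gyroscope and
#' magnetometer) of every node by that node's NEU rotation. Labels,
#' timing and metadata are unchanged.
#'
#' @param recording a \code{fall_recording}.
#' @param params per-node calibration list from
#'   \code{\link{calibrate_recording}} (must cover every node present).
#' @return the calibrated \code{fall_recording}.
#' @export
apply_calibration <- function(recording, params) {
  stopifnot(inherits(recording, "fall_recording"))
  missing_nodes <- setdiff(names(recording$streams), names(params))
  if (length(missing_nodes)) {
    stop("missing calibration for node(s): ",
         paste(missing_nodes, collapse = ", "))
  }
  for (nd in names(recording$streams)) {
    R <- params[[nd]]$r_neu
    st <- recording$streams[[nd]]
    for (ch in c("accel", "gyro", "mag")) {
      rotated <- st[[ch]] %*% t(R)
      colnames(rotated) <- colnames(st[[ch]])
      st[[ch]] <- rotated
    }
    recording$streams[[nd]] <- st
  }
  recording$calibrated <- TRUE
  recording
}
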