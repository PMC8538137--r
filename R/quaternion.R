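# Quaternion and rotation utilities. Quaternions are numeric length-4
# vectors (w, x, y, z), scalar part first, and represent rotations from
# the sensor (body) frame to the world frame: v_world = R(q) %*% v_body.

#' Normalize a quaternion to unit length
#'
#' @param q numeric length-4 quaternion (w, x, y, z).
#' @return unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Hamilton product of two quaternions
#'
#' @param p,q numeric length-4 quaternions (w, x, y, z).
#' @return quaternion p * q.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Quaternion from an axis-angle rotation
#'
#' @param axis numeric length-3 rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return unit quaternion (w, x, y, z).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis * axis))
  if (n == 0) stop("rotation axis must be non-zero")
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Builds the direction-cosine matrix of a unit quaternion
#' \code{q = (w, x, y, z)}:
#' \deqn{R(q) = \begin{pmatrix}
#'   2w^2+2x^2-1 & 2xy-2zw & 2xz+2yw \\
#'   2xy+2zw & 2w^2+2y^2-1 & 2yz-2xw \\
#'   2xz-2yw & 2yz+2xw & 2w^2+2z^2-1 \end{pmatrix}}
#' so that \code{R \%*\% v} rotates a body-frame vector into the world
#' frame.
#'
#' @param q numeric length-4 quaternion; renormalized if its norm is
#'   within 1e-6 of 1, otherwise an error.
#' @return 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
quaternion_to_rotation <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q * q))
  if (n == 0) stop("zero quaternion has no rotation")
  if (abs(n - 1) > 1e-6) stop("quaternion is not unit length (|q| = ", signif(n, 6), ")")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    2 * w^2 + 2 * x^2 - 1, 2 * x * y - 2 * z * w, 2 * x * z + 2 * y * w,
    2 * x * y + 2 * z * w, 2 * w^2 + 2 * y^2 - 1, 2 * y * z - 2 * x * w,
    2 * x * z - 2 * y * w, 2 * y * z + 2 * x * w, 2 * w^2 + 2 * z^2 - 1),
    nrow = 3, byrow = TRUE)
}

#' Convert a unit quaternion to intrinsic Z-Y'-X'' Euler angles
#'
#' Decomposes the rotation as yaw about the world vertical, then pitch
#' about the intermediate lateral axis, then roll about the body
#' longitudinal axis. The pitch argument is clamped to [-1, 1] so inputs
#' near gimbal lock return finite angles.
#'
#' @param q numeric length-4 unit quaternion (w, x, y, z).
#' @return named numeric vector \code{c(roll, pitch, yaw)} in degrees.
#' @export
quaternion_to_euler <- function(q) {
  stopifnot(length(q) == 4)
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  s <- 2 * (w * y - z * x)
  pitch <- asin(pmin(1, pmax(-1, s)))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
}

#' Euler angles (Z-Y'-X'' convention) to quaternion
#'
#' @param roll,pitch,yaw angles in degrees.
#' @return unit quaternion (w, x, y, z).
#' @export
euler_to_quaternion <- function(roll, pitch, yaw) {
  h <- c(roll, pitch, yaw) * pi / 360
  cr <- cos(h[1]); sr <- sin(h[1])
  cp <- cos(h[2]); sp <- sin(h[2])
  cy <- cos(h[3]); sy <- sin(h[3])
  c(cr * cp * cy + sr * sp * sy,
    sr * cp * cy - cr * sp * sy,
    cr * sp * cy + sr * cp * sy,
    cr * cp * sy - sr * sp * cy)
}

#' Rotation matrix to quaternion (Shepperd's method)
#'
#' @param R 3x3 rotation matrix.
#' @return unit quaternion (w, x, y, z) with non-negative scalar part.
#' @keywords internal
rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Rotate body-frame vectors by a quaternion
#'
#' @param q unit quaternion (body to world).
#' @param v length-3 vector or n x 3 matrix of body-frame vectors.
#' @return rotated vector(s) in the world frame.
#' @keywords internal
quat_rotate <- function(q, v) {
  R <- quaternion_to_rotation(q)
  if (is.matrix(v)) v %*% t(R) else as.numeric(R %*% v)
}

# angle in degrees between two rotations (geodesic distance on SO(3))
rotation_angle_deg <- function(Ra, Rb) {
  ctheta <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(pmin(1, pmax(-1, ctheta))) * 180 / pi
}

# rotation about a unit axis by an angle in degrees
axis_angle_rotation <- function(axis, angle_deg) {
  quaternion_to_rotation(quat_from_axis_angle(axis, angle_deg))
}
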