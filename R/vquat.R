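# Vectorized quaternion helpers used by the kinematic simulator.
# Quaternion series are n x 4 matrices (w, x, y, z), one row per time.

vq_mult <- function(A, B) {
  cbind(A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
        A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
        A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
        A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1])
}

vq_conj <- function(A) cbind(A[, 1], -A[, 2], -A[, 3], -A[, 4])

# unit axis (length 3), angles_deg vector -> n x 4
vq_axis_angle <- function(axis, angles_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angles_deg * pi / 360
  s <- sin(half)
  cbind(cos(half), s * axis[1], s * axis[2], s * axis[3])
}

# rotate rows of V (n x 3, or a single length-3 vector recycled) by rows of Q
vq_rotate <- function(Q, V) {
  if (!is.matrix(V)) V <- matrix(V, nrow(Q), 3, byrow = TRUE)
  w <- Q[, 1]; qv <- Q[, 2:4, drop = FALSE]
  # v' = v + 2w (qv x v) + 2 qv x (qv x v)
  cr1 <- cbind(qv[, 2] * V[, 3] - qv[, 3] * V[, 2],
               qv[, 3] * V[, 1] - qv[, 1] * V[, 3],
               qv[, 1] * V[, 2] - qv[, 2] * V[, 1])
  tmp <- cbind(w * V[, 1] + cr1[, 1], w * V[, 2] + cr1[, 2], w * V[, 3] + cr1[, 3])
  cr2 <- cbind(qv[, 2] * tmp[, 3] - qv[, 3] * tmp[, 2],
               qv[, 3] * tmp[, 1] - qv[, 1] * tmp[, 3],
               qv[, 1] * tmp[, 2] - qv[, 2] * tmp[, 1])
  V + 2 * cr2
}

# inverse rotation (world -> body)
vq_rotate_inv <- function(Q, V) vq_rotate(vq_conj(Q), V)

vq_normalize <- function(Q) Q / sqrt(rowSums(Q^2))

# body angular rate (rad/s) from a quaternion series by central differences
vq_angular_rate <- function(Q, dt) {
  n <- nrow(Q)
  im <- c(1, 1:(n - 1)); ip <- c(2:n, n)
  span <- (ip - im) * dt
  dq <- vq_mult(vq_conj(Q[im, , drop = FALSE]), Q[ip, , drop = FALSE])
  # enforce w >= 0 so the extracted angle is the short way around
  flip <- dq[, 1] < 0
  dq[flip, ] <- -dq[flip, ]
  vn <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, dq[, 1])
  scale <- ifelse(vn > 1e-12, ang / (vn * span), 0)
  dq[, 2:4, drop = FALSE] * scale
}
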