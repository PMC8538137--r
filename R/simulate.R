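# Kinematic simulator for labeled multi-IMU fall / fall-like recordings.
#
# The body is an inverted pendulum pivoting at the ankles; limb nodes get
# an extra articulation rotation about their proximal joint. Raw sensor
# streams are synthesized from the ground-truth node orientations R(t)
# and positions p(t):
#   accel = R't (p_ddot - g_vec) + bias + noise   (specific force, m/s^2)
#   gyro  = omega_body + bias + noise             (deg/s)
#   mag   = R't m_earth + bias + noise            (uT)
# with g_vec = (0, 0, -9.81) in the north-east-up world frame, so a
# static sensor reports +9.81 m/s^2 along its body-frame up axis.

.GRAVITY <- 9.81
.EARTH_MAG <- c(30, 0, -40)          # uT, horizontal north + downward dip
.FALL_RATE_THRESHOLD <- 20           # deg/s trunk rate that starts the fall label

#' Sensor noise model
#'
#' Per-sample white Gaussian noise plus a per-axis constant bias drawn
#' once per trial and node. All values are standard deviations.
#'
#' @param accel_sd accelerometer noise, m/s^2.
#' @param gyro_sd gyroscope noise, deg/s.
#' @param mag_sd magnetometer noise, uT.
#' @param accel_bias_sd,gyro_bias_sd,mag_bias_sd bias draw scales.
#' @return object of class \code{noise_params}.
#' @export
noise_params <- function(accel_sd = 0.15, gyro_sd = 0.5, mag_sd = 0.5,
                         accel_bias_sd = 0.05, gyro_bias_sd = 0.2,
                         mag_bias_sd = 0.3) {
  p <- list(accel_sd = accel_sd, gyro_sd = gyro_sd, mag_sd = mag_sd,
            accel_bias_sd = accel_bias_sd, gyro_bias_sd = gyro_bias_sd,
            mag_bias_sd = mag_bias_sd)
  if (any(unlist(p) < 0)) stop("noise standard deviations must be >= 0")
  structure(p, class = "noise_params")
}

#' @rdname noise_params
#' @export
zero_noise <- function() {
  noise_params(0, 0, 0, 0, 0, 0)
}

#' Subject anthropometrics
#'
#' Segment lengths are standard anthropometric fractions of stature.
#' The study population spans statures of 1.70-1.88 m.
#'
#' @param subject_id integer identifier.
#' @param height stature in meters, in [1.70, 1.88].
#' @return object of class \code{subject_params} with named
#'   \code{segment_lengths} (shank, thigh, torso, upper_arm, forearm).
#' @export
subject_params <- function(subject_id, height) {
  stopifnot(is.numeric(height), length(height) == 1L)
  if (height < 1.70 || height > 1.88) {
    stop("subject height must lie in [1.70, 1.88] m")
  }
  structure(list(
    subject_id = as.integer(subject_id),
    height = height,
    segment_lengths = c(shank = 0.246, thigh = 0.245, torso = 0.288,
                        upper_arm = 0.186, forearm = 0.146) * height),
    class = "subject_params")
}

# body-frame node positions (x forward, y left, z up; origin at the
# ankle pivot on the ground) and articulation groups
.node_layout <- function(h) {
  pos <- rbind(
    chest   = c(0.06,  0.00, 0.72 * h),
    elbow_l = c(0.02,  0.22, 0.63 * h),
    elbow_r = c(0.02, -0.22, 0.63 * h),
    wrist_l = c(0.07,  0.24, 0.50 * h),
    wrist_r = c(0.07, -0.24, 0.50 * h),
    thigh_l = c(0.06,  0.11, 0.45 * h),
    thigh_r = c(0.06, -0.11, 0.45 * h),
    ankle_l = c(0.02,  0.08, 0.07 * h),
    ankle_r = c(0.02, -0.08, 0.07 * h))
  joints <- rbind(
    chest   = c(0, 0, 0),
    elbow_l = c(0,  0.19, 0.82 * h), elbow_r = c(0, -0.19, 0.82 * h),
    wrist_l = c(0,  0.19, 0.82 * h), wrist_r = c(0, -0.19, 0.82 * h),
    thigh_l = c(0,  0.09, 0.53 * h), thigh_r = c(0, -0.09, 0.53 * h),
    ankle_l = c(0,  0.09, 0.53 * h), ankle_r = c(0, -0.09, 0.53 * h))
  group <- c(chest = "trunk", elbow_l = "arm_l", elbow_r = "arm_r",
             wrist_l = "arm_l", wrist_r = "arm_r",
             thigh_l = "leg_l", thigh_r = "leg_r",
             ankle_l = "shank_l", ankle_r = "shank_r")
  list(pos = pos, joints = joints, group = group)
}

# ---- piecewise schedules ----------------------------------------------

smooth01 <- function(s) { s <- pmin(1, pmax(0, s)); s * s * (3 - 2 * s) }
acc01 <- function(s) { s <- pmin(1, pmax(0, s)); s * s }

# segs: list of c(t0, t1, from, to, type) with type 1 = smooth, 2 = accelerating
eval_piecewise <- function(t, segs, init = 0) {
  val <- rep(init, length(t))
  for (sg in segs) {
    s <- (t - sg[1]) / (sg[2] - sg[1])
    r <- if (sg[5] == 2) acc01(s) else smooth01(s)
    idx <- t >= sg[1]
    val[idx] <- sg[3] + (sg[4] - sg[3]) * r[idx]
  }
  val
}

# envelope-windowed sinusoid, zero outside [t0, t1]
osc <- function(t, t0, t1, amp, freq, phase = 0, ramp = 0.4) {
  env <- smooth01((t - t0) / ramp) * smooth01((t1 - t) / ramp)
  amp * sin(2 * pi * freq * (t - t0) + phase) * env
}

# Activity schedule: trunk tilt angle/axis, vertical drop, limb angles,
# fall segment (for labeling) and impact events. Times in seconds from
# trial start; ts is the activity onset. jit() applies per-trial
# duration jitter.
.activity_schedule <- function(activity, ts, jit) {
  ax_fwd <- c(0, 1, 0); ax_back <- c(0, -1, 0)
  ax_left <- c(-1, 0, 0); ax_right <- c(1, 0, 0)
  sched <- list(axis = ax_fwd, theta = list(), drop = list(),
                limb = list(), gait = NULL, fall_seg = NULL,
                impacts = NULL)
  seg <- function(t0, dur, from, to, type = 2) c(t0, t0 + dur, from, to, type)
  switch(activity,
    F1 = {  # forward onto the knees, then torso to the ground
      d1 <- jit(0.65); dp <- jit(0.45); d2 <- jit(0.5)
      s1 <- seg(ts, d1, 0, 50); s2 <- seg(ts + d1 + dp, d2, 50, 90)
      sched$theta <- list(s1, s2)
      sched$limb$arm <- list(seg(ts, d1, 0, 20, 1))
      sched$fall_seg <- c(s1[1], s1[2])
      sched$impacts <- rbind(c(s1[2], 15), c(s2[2], 30))
    },
    F2 = {  # forward onto the hands
      d1 <- jit(0.9)
      s1 <- seg(ts, d1, 0, 90)
      sched$theta <- list(s1)
      sched$limb$arm <- list(seg(ts + 0.15 * d1, 0.85 * d1, 0, 60, 1))
      sched$fall_seg <- c(s1[1], s1[2])
      sched$impacts <- rbind(c(s1[2], 35))
    },
    F3 = ,
    F4 = {  # inclined lateral falls
      d1 <- jit(0.85)
      s1 <- seg(ts, d1, 0, 90)
      sched$axis <- if (activity == "F3") ax_left else ax_right
      sched$theta <- list(s1)
      sched$fall_seg <- c(s1[1], s1[2])
      sched$impacts <- rbind(c(s1[2], 32))
    },
    F5 = {  # slow forward fall with a crouch first
      dc <- jit(1.6); d1 <- jit(1.0)
      sc <- seg(ts, dc, 0, 25, 1); s1 <- seg(ts + dc, d1, 25, 90)
      sched$theta <- list(sc, s1)
      sched$drop <- list(seg(ts, dc, 0, -0.25, 1))
      sched$limb$leg <- list(seg(ts, dc, 0, 50, 1))
      sched$fall_seg <- c(s1[1], s1[2])
      sched$impacts <- rbind(c(s1[2], 28))
    },
    F6 = {  # backward fall onto the seat, then lying back
      d1 <- jit(0.7); dp <- jit(0.4); d2 <- jit(0.6)
      s1 <- seg(ts, d1, 0, 55); s2 <- seg(ts + d1 + dp, d2, 55, 90)
      sched$axis <- ax_back
      sched$theta <- list(s1, s2)
      sched$fall_seg <- c(s1[1], s1[2])
      sched$impacts <- rbind(c(s1[2], 18), c(s2[2], 12))
    },
    FL1 = {  # crouch down, hold, stand up
      dd <- jit(1.2); dh <- jit(1.0); du <- jit(1.2)
      t1 <- ts + dd + dh
      sched$theta <- list(seg(ts, dd, 0, 20, 1), seg(t1, du, 20, 0, 1))
      sched$drop <- list(seg(ts, dd, 0, -0.35, 1), seg(t1, du, -0.35, 0, 1))
      sched$limb$leg <- list(seg(ts, dd, 0, 70, 1), seg(t1, du, 70, 0, 1))
    },
    FL2 = {  # walk with a stoop; trunk trajectory deliberately mimics
             # the slow fall's crouch (same angle and rate range, slow
             # bowing straddling the early-fall rate threshold) so only
             # the lower body separates the two
      dsk <- jit(1.5); dw <- jit(3.0); f <- jit(0.9)
      tw0 <- ts + dsk; tw1 <- tw0 + dw
      sched$theta <- list(seg(ts, dsk, 0, 25, 1), seg(tw1, jit(0.8), 25, 0, 1))
      sched$drop <- list(seg(ts, dsk, 0, -0.12, 1),
                         seg(tw1, jit(0.8), -0.12, 0, 1))
      sched$gait <- list(t0 = tw0, t1 = tw1, freq = f,
                         thigh = 28, ankle = 35, arm = 15,
                         trunk_bob = 3, drop_bob = 0.02,
                         bow = 10, bow_freq = 0.35)
    },
    FL3 = {  # sit down and stay seated
      dl <- jit(0.6); ds <- jit(1.0)
      sched$theta <- list(seg(ts, dl, 0, 15, 1), seg(ts + dl, ds, 15, -5, 1))
      sched$drop <- list(seg(ts + dl, ds, 0, -0.45, 1))
      sched$limb$leg <- list(seg(ts + dl, ds, 0, 85, 1))
      sched$impacts <- rbind(c(ts + dl + ds, 6))
    },
    stop("unknown activity code: ", activity)
  )
  sched
}

# ---- main simulator ----------------------------------------------------

#' Simulate one multi-node IMU recording
#'
#' Generates a labeled trial for one activity: a quasi-static standing
#' prefix (2 s), a short postural sway, the scripted movement, and a
#' still tail. All nine nodes are synthesized from shared ground-truth
#' kinematics; the whole trial is rotated by \code{heading} and each
#' node gets a random mounting orientation, so downstream calibration is
#' genuinely exercised. For fall activities the early-fall phase — from
#' the instant the trunk angular rate first exceeds 20 deg/s until the
#' first ground contact — is labeled 1; fall-like trials carry no
#' positive labels.
#'
#' @param activity one of \code{\link{activity_codes}}.
#' @param subject a \code{\link{subject_params}} object.
#' @param heading trial heading in degrees (rotation about the world
#'   vertical).
#' @param noise a \code{\link{noise_params}} object.
#' @param seed integer seed; identical arguments give bit-identical
#'   recordings.
#' @param sample_rate output sampling rate in Hz (>= 10; default 15).
#' @param duration trial length in seconds.
#' @return object of class \code{fall_recording}: per-node streams
#'   (\code{accel}, \code{gyro}, \code{mag} matrices), time vector,
#'   per-sample labels, static prefix length, and a \code{truth} block
#'   with the generator's ground-truth orientations.
#' @export
simulate_recording <- function(activity, subject = subject_params(1, 1.78),
                               heading = 0, noise = noise_params(),
                               seed = 1L, sample_rate = 15, duration = 8) {
  stopifnot(inherits(subject, "subject_params"), sample_rate >= 10)
  if (!inherits(noise, "noise_params")) stop("noise must be a noise_params object")
  if (!activity %in% activity_codes()) stop("unknown activity code: ", activity)

  with_preserved_seed(seed, {
    fs <- sample_rate
    os <- max(2L, as.integer(ceiling(240 / fs)))   # fine oversampling factor
    dt_f <- 1 / (fs * os)
    n <- as.integer(round(duration * fs))
    n_f <- n * os
    t_f <- (seq_len(n_f) - 1) * dt_f
    coarse <- seq(1L, n_f, by = os)
    t_c <- t_f[coarse]

    static_dur <- 2.0
    static_len <- as.integer(round(static_dur * fs))
    jit <- function(x) x * runif(1, 0.9, 1.1)
    ts <- static_dur + 0.5
    sch <- .activity_schedule(activity, ts, jit)

    # trunk tilt (deg), with postural sway between prefix and onset
    theta <- eval_piecewise(t_f, sch$theta)
    theta <- theta + osc(t_f, static_dur, ts + 0.1, 0.8, 0.5)
    drop <- eval_piecewise(t_f, sch$drop)
    leg <- if (!is.null(sch$limb$leg)) eval_piecewise(t_f, sch$limb$leg) else numeric(n_f)
    arm <- if (!is.null(sch$limb$arm)) eval_piecewise(t_f, sch$limb$arm) else numeric(n_f)
    leg_l <- leg; leg_r <- leg; arm_l <- arm; arm_r <- arm
    if (!is.null(sch$gait)) {
      g <- sch$gait
      leg_l <- leg_l + osc(t_f, g$t0, g$t1, g$thigh, g$freq)
      leg_r <- leg_r - osc(t_f, g$t0, g$t1, g$thigh, g$freq)
      arm_l <- arm_l - osc(t_f, g$t0, g$t1, g$arm, g$freq)
      arm_r <- arm_r + osc(t_f, g$t0, g$t1, g$arm, g$freq)
      theta <- theta + osc(t_f, g$t0, g$t1, g$trunk_bob, 2 * g$freq)
      drop <- drop + osc(t_f, g$t0, g$t1, g$drop_bob, 2 * g$freq)
      if (!is.null(g$bow)) {   # slow bowing of the stooped trunk
        theta <- theta + osc(t_f, g$t0, g$t1, g$bow, g$bow_freq, ramp = 0.8)
      }
    }
    # shanks (ankle nodes) swing with the legs only during gait; in
    # squat/sit the feet stay planted
    if (is.null(sch$gait)) {
      shank_l <- numeric(n_f); shank_r <- numeric(n_f)
    } else {
      shank_l <- leg_l; shank_r <- leg_r
    }

    # ground-truth orientations per articulation group
    q_head <- vq_axis_angle(c(0, 0, 1), rep(heading, n_f))
    q_trunk <- vq_mult(q_head, vq_axis_angle(sch$axis, theta))
    limb_angle <- list(trunk = numeric(n_f),
                       arm_l = arm_l, arm_r = arm_r,
                       leg_l = leg_l, leg_r = leg_r,
                       shank_l = shank_l, shank_r = shank_r)
    q_group <- lapply(limb_angle, function(phi) {
      if (all(phi == 0)) q_trunk
      else vq_mult(q_trunk, vq_axis_angle(c(0, -1, 0), phi))
    })

    lay <- .node_layout(subject$height)
    nodes <- node_ids()

    # impact transients: decaying world-frame oscillation, mostly vertical
    imp_acc <- matrix(0, n_f, 3)
    if (!is.null(sch$impacts)) {
      horiz <- vq_rotate(q_head[1, , drop = FALSE],
                         c(sch$axis[2], -sch$axis[1], 0))[1, ]  # fall direction
      for (k in seq_len(nrow(sch$impacts))) {
        t0 <- sch$impacts[k, 1]; sev <- sch$impacts[k, 2]
        rel <- t_f - t0
        act <- rel >= 0 & rel < 0.25
        pulse <- numeric(n_f)
        pulse[act] <- sev * exp(-rel[act] / 0.04) * cos(2 * pi * 12 * rel[act])
        dir <- c(0.4 * horiz[1], 0.4 * horiz[2], 1)
        dir <- dir / sqrt(sum(dir^2))
        imp_acc <- imp_acc + outer(pulse, dir)
      }
    }

    # labels: early-fall phase on the coarse grid
    labels <- integer(n)
    if (!is.null(sch$fall_seg)) {
      rate <- c(0, abs(diff(theta)) / dt_f)
      inseg <- t_f >= sch$fall_seg[1] & t_f <= sch$fall_seg[2]
      onset_idx <- which(inseg & rate > .FALL_RATE_THRESHOLD)[1]
      t_on <- t_f[onset_idx]
      labels[t_c >= t_on & t_c <= sch$fall_seg[2]] <- 1L
    }

    g_vec <- c(0, 0, -.GRAVITY)
    streams <- vector("list", length(nodes)); names(streams) <- nodes
    truth_q <- vector("list", length(nodes)); names(truth_q) <- nodes

    for (nd in nodes) {
      grp <- lay$group[[nd]]
      qg <- q_group[[grp]]
      p0 <- lay$pos[nd, ]; joint <- lay$joints[nd, ]
      phi <- limb_angle[[grp]] * pi / 180
      # articulation about the joint (axis -y: positive = forward swing)
      v <- p0 - joint
      p_art <- cbind(joint[1] + v[1] * cos(phi) - v[3] * sin(phi),
                     joint[2] + v[2],
                     joint[3] + v[1] * sin(phi) + v[3] * cos(phi))
      p_w <- vq_rotate(q_trunk, p_art)
      p_w[, 3] <- p_w[, 3] + drop

      # linear acceleration by central second difference on the fine grid
      acc_w <- matrix(0, n_f, 3)
      mid <- 2:(n_f - 1)
      acc_w[mid, ] <- (p_w[mid + 1, ] - 2 * p_w[mid, ] + p_w[mid - 1, ]) / dt_f^2
      acc_w <- acc_w + imp_acc

      # random mounting orientation, fixed over the trial
      qm <- quat_normalize(rnorm(4))
      q_node <- vq_mult(qg, matrix(qm, n_f, 4, byrow = TRUE))
      q_node <- vq_normalize(q_node)

      f_world <- acc_w - matrix(g_vec, n_f, 3, byrow = TRUE)
      accel <- vq_rotate_inv(q_node, f_world)
      gyro <- vq_angular_rate(q_node, dt_f) * 180 / pi
      mag <- vq_rotate_inv(q_node, .EARTH_MAG)

      ac <- accel[coarse, , drop = FALSE]
      gy <- gyro[coarse, , drop = FALSE]
      mg <- mag[coarse, , drop = FALSE]
      if (noise$accel_sd > 0 || noise$accel_bias_sd > 0) {
        ac <- ac + matrix(rnorm(3, 0, noise$accel_bias_sd), n, 3, byrow = TRUE) +
          matrix(rnorm(3 * n, 0, noise$accel_sd), n, 3)
      }
      if (noise$gyro_sd > 0 || noise$gyro_bias_sd > 0) {
        gy <- gy + matrix(rnorm(3, 0, noise$gyro_bias_sd), n, 3, byrow = TRUE) +
          matrix(rnorm(3 * n, 0, noise$gyro_sd), n, 3)
      }
      if (noise$mag_sd > 0 || noise$mag_bias_sd > 0) {
        mg <- mg + matrix(rnorm(3, 0, noise$mag_bias_sd), n, 3, byrow = TRUE) +
          matrix(rnorm(3 * n, 0, noise$mag_sd), n, 3)
      }
      colnames(ac) <- c("ax", "ay", "az")
      colnames(gy) <- c("gx", "gy", "gz")
      colnames(mg) <- c("mx", "my", "mz")
      streams[[nd]] <- list(accel = ac, gyro = gy, mag = mg)
      truth_q[[nd]] <- q_node[coarse, , drop = FALSE]
    }

    structure(list(
      subject = subject, activity = activity,
      is_fall = is_fall_activity(activity),
      trial_index = 1L, sample_rate = fs, t = t_c,
      streams = streams, labels = labels,
      static_prefix_len = static_len, heading_deg = heading,
      noise = noise, seed = as.integer(seed),
      truth = list(q = truth_q, theta_deg = theta[coarse],
                   fall_seg = sch$fall_seg)),
      class = "fall_recording")
  })
}

#' @export
print.fall_recording <- function(x, ...) {
  cat(sprintf("<fall_recording> subject %d, activity %s (%s), trial %d\n",
              x$subject$subject_id, x$activity,
              if (x$is_fall) "fall" else "fall-like", x$trial_index))
  cat(sprintf("  %d samples at %g Hz over %d nodes; %d fall-labeled samples\n",
              length(x$t), x$sample_rate, length(x$streams), sum(x$labels)))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' Draws per-subject anthropometrics (statures uniform in 1.70-1.88 m)
#' and simulates every requested trial with a random heading; all
#' randomness is derived from \code{seed}, so the dataset is fully
#' reproducible. The default trial counts are those of the study
#' protocol (\code{\link{default_trial_counts}}): 35 trials per subject,
#' 490 for 14 subjects.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param trials_per_activity named integer vector, activity -> trials
#'   per subject.
#' @param noise a \code{\link{noise_params}} object.
#' @param seed integer master seed.
#' @param sample_rate,duration passed to \code{\link{simulate_recording}}.
#' @return list of \code{fall_recording} objects.
#' @export
generate_dataset <- function(n_subjects = 14,
                             trials_per_activity = default_trial_counts(),
                             noise = noise_params(), seed = 1L,
                             sample_rate = 15, duration = 8) {
  stopifnot(n_subjects >= 0)
  if (length(trials_per_activity) == 0) stop("empty trial map")
  if (is.null(names(trials_per_activity)) ||
      !all(names(trials_per_activity) %in% activity_codes())) {
    stop("trials_per_activity must be named with activity codes")
  }
  if (any(trials_per_activity < 0)) stop("trial counts must be >= 0")
  if (n_subjects == 0) return(list())

  plan <- with_preserved_seed(seed, {
    heights <- runif(n_subjects, 1.70, 1.88)
    n_trials <- n_subjects * sum(trials_per_activity)
    list(heights = heights,
         headings = runif(n_trials, 0, 360),
         child_seeds = sample.int(.Machine$integer.max - 1L, n_trials))
  })

  out <- vector("list", n_subjects * sum(trials_per_activity))
  k <- 0L
  for (s in seq_len(n_subjects)) {
    subj <- subject_params(s, plan$heights[s])
    for (act in names(trials_per_activity)) {
      for (tr in seq_len(trials_per_activity[[act]])) {
        k <- k + 1L
        rec <- simulate_recording(act, subj, heading = plan$headings[k],
                                  noise = noise, seed = plan$child_seeds[k],
                                  sample_rate = sample_rate,
                                  duration = duration)
        rec$trial_index <- tr
        out[[k]] <- rec
      }
    }
  }
  out
}

# evaluate code under a given seed without disturbing the caller's RNG
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
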