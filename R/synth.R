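# Synthetic session generator: scripted posture motions emulating the
# assembly-operation protocol (seven ~2-minute bolt-installation tasks with
# preparation and break periods), and a forward sensor model producing the
# six-tracker IMU streams with realistic noise. This module is the stand-in
# for the unavailable experimental recordings: it states the world the
# acceptance suite measures.

DEFAULT_SEED <- 20240686L

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Session script of the operation-posture collection protocol
#'
#' Ordered task list: 60 s preparation; bolt installation in each of the
#' seven postures (121.8, 123.25, 116.55, 140.6, 118.35, 86.5 and 96.3 s for
#' labels 1-5 with a 60 s break before the squatting task, then 6 and 7);
#' `label = NA` marks unlabeled (excluded) periods.
#'
#' @param scale Multiplier on every duration (compute scaling for desk-size
#'   runs; 1 = the full protocol).
#' @param sample_rate Hz.
#' @return Object of class `session_script`: data.frame `task`, `label`,
#'   `duration_ms` plus the rate.
#' @export
table3_script <- function(scale = 1, sample_rate = 100) {
  stopifnot(scale > 0, sample_rate > 0)
  df <- data.frame(
    task = c("preparation",
             "install bolts standing", "install bolts slightly bending",
             "install bolts deep bending", "install bolts half squatting",
             "break",
             "install bolts squatting", "install bolts sitting",
             "install bolts supine"),
    label = c(NA, 1L, 2L, 3L, 4L, NA, 5L, 6L, 7L),
    duration_ms = c(60000, 121800, 123250, 116550, 140600, 60000,
                    118350, 86500, 96300) * scale
  )
  structure(list(tasks = df, sample_rate = sample_rate),
            class = "session_script")
}

#' Custom session script
#' @param labels Integer posture labels (NA = excluded period).
#' @param duration_ms Durations, one per task.
#' @param sample_rate Hz.
#' @export
session_script <- function(labels, duration_ms, sample_rate = 100) {
  stopifnot(length(labels) == length(duration_ms), all(duration_ms > 0))
  df <- data.frame(task = ifelse(is.na(labels), "excluded",
                                 POSTURE_NAMES[labels]),
                   label = as.integer(labels), duration_ms = duration_ms)
  structure(list(tasks = df, sample_rate = sample_rate),
            class = "session_script")
}

# Minimum-jerk interpolation profile on [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Scalar waypoint-drift process: new waypoint every 2-5 s drawn uniformly in
# [lo, hi], minimum-jerk interpolation between waypoints, sampled at `tt`.
waypoint_drift <- function(tt, lo, hi) {
  dur <- tt[length(tt)]
  wt <- 0
  while (wt[length(wt)] < dur) wt <- c(wt, wt[length(wt)] + stats::runif(1, 2, 5))
  wv <- stats::runif(length(wt), lo, hi)
  idx <- findInterval(tt, wt, rightmost.closed = FALSE)
  idx <- pmin(idx, length(wt) - 1)
  tau <- (tt - wt[idx]) / (wt[idx + 1] - wt[idx])
  wv[idx] + min_jerk(pmin(1, pmax(0, tau))) * (wv[idx + 1] - wv[idx])
}

# Band-limited postural tremor: sum of random-phase sinusoids in 1-4 Hz
# with a total RMS of `rms` degrees.
tremor <- function(tt, rms = 0.5, n_comp = 6, f_lo = 1, f_hi = 4) {
  amp <- rms * sqrt(2 / n_comp)
  out <- numeric(length(tt))
  for (k in seq_len(n_comp)) {
    f <- stats::runif(1, f_lo, f_hi)
    ph <- stats::runif(1, 0, 2 * pi)
    out <- out + amp * sin(2 * pi * f * tt + ph)
  }
  out
}

# Convert bend-angle channels (degrees) to the 9 x 3 joint-angle matrix
# (radians): torso split equally between lumbar and thoracic (negative
# pitch leans the chest forward in the Y-down frame), hip pitch = hip bend,
# knee pitch = -knee bend.
bends_to_angles <- function(bends) {
  n <- nrow(bends)
  angles <- array(0, c(n, length(JOINT_ORDER), 3),
                  dimnames = list(NULL, JOINT_ORDER, c("yaw", "pitch", "roll")))
  d2r <- pi / 180
  angles[, "lumbar", "pitch"] <- -bends[, "torso"] / 2 * d2r
  angles[, "thoracic", "pitch"] <- -bends[, "torso"] / 2 * d2r
  angles[, "l_hip", "pitch"] <- bends[, "hip_l"] * d2r
  angles[, "r_hip", "pitch"] <- bends[, "hip_r"] * d2r
  angles[, "l_knee", "pitch"] <- -bends[, "knee_l"] * d2r
  angles[, "r_knee", "pitch"] <- -bends[, "knee_r"] * d2r
  angles
}

#' Generate a single-posture motion trace
#'
#' Joint bends stay inside the posture's taxonomy ranges shrunk by a 10%
#' margin on each side. The motion is slow waypoint drift (new waypoint
#' every 2-5 s, minimum-jerk interpolation) plus band-limited postural
#' tremor (0.5 deg RMS, 1-4 Hz), clamped to the shrunk range; left and right
#' sides drift independently. Deterministic given `seed`.
#'
#' @param label Posture label 1-7.
#' @param duration Seconds.
#' @param rate Hz (default 100).
#' @param seed RNG seed.
#' @param margin Fractional range shrink per side.
#' @param labeled If `FALSE` frames are marked excluded (`NA` label), as in
#'   preparation/break periods.
#' @return Object of class `motion_trace`: `t`, `angles` (n x 9 x 3, rad),
#'   `bends` (n x 5, deg), `labels`, `rate`.
#' @export
generate_posture_trajectory <- function(label, duration, rate = 100,
                                        seed = DEFAULT_SEED, margin = 0.1,
                                        labeled = TRUE) {
  if (!label %in% 1:7) stop("invalid posture label: ", label)
  n <- max(3L, round(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  r <- POSTURE_RANGES[label, ]
  shrunk <- function(lo, hi) {
    w <- (hi - lo) * margin
    c(lo + w, hi - w)
  }
  tor <- shrunk(r["torso_lo"], r["torso_hi"])
  hip <- shrunk(r["hip_lo"], r["hip_hi"])
  kne <- shrunk(r["knee_lo"], r["knee_hi"])
  bends <- with_seed(seed, {
    chan <- function(rng) {
      pmin(rng[2], pmax(rng[1], waypoint_drift(tt, rng[1], rng[2]) + tremor(tt)))
    }
    cbind(torso = chan(tor),
          hip_l = chan(hip), hip_r = chan(hip),
          knee_l = chan(kne), knee_r = chan(kne))
  })
  structure(list(t = tt, angles = bends_to_angles(bends), bends = bends,
                 labels = if (labeled) rep(as.integer(label), n) else rep(NA_integer_, n),
                 rate = rate),
            class = "motion_trace")
}

# Concatenate motion traces with minimum-jerk blends of `transition_s`
# seconds between them, blend frames labeled excluded.
concat_traces <- function(traces, rate, transition_s = 2) {
  pieces_b <- list(); pieces_l <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (i > 1 && transition_s > 0) {
      a <- pieces_b[[length(pieces_b)]]
      from <- a[nrow(a), , drop = FALSE]
      to <- tr$bends[1, , drop = FALSE]
      m <- round(transition_s * rate)
      s <- min_jerk(seq_len(m) / (m + 1))
      blend <- from[rep(1, m), , drop = FALSE] +
        s %o% (as.numeric(to) - as.numeric(from))
      colnames(blend) <- colnames(a)
      pieces_b[[length(pieces_b) + 1]] <- blend
      pieces_l[[length(pieces_l) + 1]] <- rep(NA_integer_, m)
    }
    pieces_b[[length(pieces_b) + 1]] <- tr$bends
    pieces_l[[length(pieces_l) + 1]] <- tr$labels
  }
  bends <- do.call(rbind, pieces_b)
  labels <- unlist(pieces_l)
  n <- nrow(bends)
  structure(list(t = (seq_len(n) - 1) / rate, angles = bends_to_angles(bends),
                 bends = bends, labels = labels, rate = rate),
            class = "motion_trace")
}

#' Build a full scripted session
#'
#' Generates one trace per task of the script (preparation/break tasks are
#' standing-like motion marked excluded) and concatenates them with 2 s
#' minimum-jerk transitions labeled excluded, so every labeled segment keeps
#' its scripted duration.
#'
#' @param script A [table3_script()] or [session_script()].
#' @param seed RNG seed; each task derives its own sub-seed.
#' @param transition_s Transition exclusion window.
#' @return A `motion_trace` covering the session.
#' @export
build_session <- function(script = table3_script(), seed = DEFAULT_SEED,
                          transition_s = 2) {
  rate <- script$sample_rate
  tasks <- script$tasks
  traces <- lapply(seq_len(nrow(tasks)), function(i) {
    lab <- tasks$label[i]
    generate_posture_trajectory(
      label = if (is.na(lab)) 1L else lab,
      duration = tasks$duration_ms[i] / 1000,
      rate = rate, seed = seed + i, labeled = !is.na(lab)
    )
  })
  out <- concat_traces(traces, rate, transition_s)
  attr(out, "script") <- tasks
  out
}

# Tracker mounting points in their segment frames (mm): chest mid-sternum,
# waist at the pelvis root, knee trackers at the knee end of the femur,
# ankle trackers at the ankle end of the tibia.
tracker_offsets_mm <- function(sk) {
  list(chest = sk$end_sites$thoracic / 2,
       waist = c(0, 0, 0),
       l_knee = c(0, 0.8 * sk$segment_lengths[["femur"]], 0),
       l_ankle = c(0, 0.8 * sk$segment_lengths[["tibia"]], 0),
       r_knee = c(0, 0.8 * sk$segment_lengths[["femur"]], 0),
       r_ankle = c(0, 0.8 * sk$segment_lengths[["tibia"]], 0))
}

#' Forward sensor model: IMU streams from a motion trace
#'
#' For each tracker the segment orientation and mounting point follow from
#' forward kinematics; the gyroscope signal is the body-frame angular
#' velocity obtained from quaternion finite differences, the accelerometer
#' signal is the body-frame specific force `q* (a_w - g_down) q` with the
#' world acceleration from second differences of the tracker position.
#' White Gaussian noise (per-sample sigma = density x sqrt(rate/2)) and the
#' configured constant biases are added. Deterministic given `seed`.
#'
#' @param trace A `motion_trace` (at least 3 frames, uniform rate).
#' @param sk A [skeleton_from_height()].
#' @param cal A [calibrate()] result (sensor = segment x mounting^-1).
#' @param noise A [sensor_noise_model()].
#' @param frame A [frame_convention()].
#' @param seed RNG seed for the sensor noise.
#' @return List with `streams` (named list of [imu_stream()]) and `truth`
#'   (named list of data.frames `t, qw..qz, px..pz, vx..vz`: true
#'   orientation, position (m) and velocity of each tracker).
#' @export
imu_from_motion <- function(trace, sk = skeleton_from_height(),
                            cal = identity_calibration(),
                            noise = sensor_noise_none(),
                            frame = frame_convention(),
                            seed = DEFAULT_SEED) {
  n <- length(trace$t)
  if (n < 3) stop("trace must have at least 3 frames")
  rate <- trace$rate
  dt <- 1 / rate
  offs <- tracker_offsets_mm(sk)
  g_down <- frame$gravity_vector

  Q <- lapply(TRACKER_IDS, function(.) matrix(0, n, 4))
  P <- lapply(TRACKER_IDS, function(.) matrix(0, n, 3))
  names(Q) <- names(P) <- TRACKER_IDS
  for (i in seq_len(n)) {
    fk <- forward_kinematics(sk, trace$angles[i, , ])
    for (tr in TRACKER_IDS) {
      jn <- TRACKER_SEGMENT[[tr]]
      q_seg <- fk$orient[[jn]]
      Q[[tr]][i, ] <- quat_mul(q_seg, quat_conj(cal$mounting_q[[tr]]))
      P[[tr]][i, ] <- (fk$pos[jn, ] + quat_rotate(q_seg, offs[[tr]])) / 1000
    }
  }

  sig <- noise_sigma(noise, g = max(9.81, sqrt(sum(g_down^2))))
  streams <- list(); truth <- list()
  for (tr in TRACKER_IDS) {
    qs <- Q[[tr]]; ps <- P[[tr]]
    w <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      if (i == 1) {
        w[i, ] <- quat_to_rotvec(quat_mul(quat_conj(qs[1, ]), qs[2, ])) / dt
      } else if (i == n) {
        w[i, ] <- quat_to_rotvec(quat_mul(quat_conj(qs[n - 1, ]), qs[n, ])) / dt
      } else {
        w[i, ] <- quat_to_rotvec(quat_mul(quat_conj(qs[i - 1, ]), qs[i + 1, ])) / (2 * dt)
      }
    }
    aw <- matrix(0, n, 3)
    aw[2:(n - 1), ] <- (ps[3:n, ] - 2 * ps[2:(n - 1), ] + ps[1:(n - 2), ]) / dt^2
    aw[1, ] <- aw[2, ]; aw[n, ] <- aw[n - 1, ]
    fb <- t(vapply(seq_len(n), function(i) {
      quat_rotate(quat_conj(qs[i, ]), aw[i, ] - g_down)
    }, numeric(3)))
    v <- matrix(0, n, 3)
    v[2:(n - 1), ] <- (ps[3:n, ] - ps[1:(n - 2), ]) / (2 * dt)
    v[1, ] <- (ps[2, ] - ps[1, ]) / dt
    v[n, ] <- (ps[n, ] - ps[n - 1, ]) / dt

    noisy <- with_seed(seed + match(tr, TRACKER_IDS), {
      list(a = fb + sweep(matrix(stats::rnorm(3 * n, sd = sig["accel"]), n, 3),
                          2, noise$accel_bias, `+`),
           g = w + sweep(matrix(stats::rnorm(3 * n, sd = sig["gyro"]), n, 3),
                         2, noise$gyro_bias, `+`))
    })
    streams[[tr]] <- imu_stream(trace$t, noisy$a, noisy$g, tr, strict = FALSE)
    validate_imu_stream(streams[[tr]])
    tdf <- data.frame(t = trace$t,
                      qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4],
                      px = ps[, 1], py = ps[, 2], pz = ps[, 3],
                      vx = v[, 1], vy = v[, 2], vz = v[, 3])
    truth[[tr]] <- tdf
  }
  list(streams = streams, truth = truth)
}
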