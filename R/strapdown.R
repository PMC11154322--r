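# Strapdown integration and drift compensation.
#
# Dead reckoning of one tracker from two consecutive IMU samples:
#   a_w(t)   = Q_t (a_b(t) - B_a) + g_down          (world acceleration; the
#              sample stores specific force, so adding the downward gravity
#              vector removes the gravity reaction)
#   wbar     = (w_t + w_{t+1}) / 2 - B_g            (average angular rate)
#   Q_{t+1}  = Q_t * exp(wbar * dt)
#   a_w(t+1) = Q_{t+1} (a_b(t+1) - B_a) + g_down
#   abar     = (a_w(t) + a_w(t+1)) / 2
#   V_{t+1}  = V_t + abar dt
#   D_{t+1}  = D_t + V_t dt + abar dt^2 / 2
# Orientation is integrated with the average angular velocity; acceleration
# is integrated trapezoidally.

#' One strapdown integration step
#'
#' Advances a [tracker_state()] across two consecutive IMU samples.
#'
#' @param state Current [tracker_state()].
#' @param s_t,s_t1 One-row data.frames (or lists) with fields
#'   `t, ax, ay, az, gx, gy, gz`; `s_t1$t > s_t$t`, `dt <= 0.1 s`.
#' @param noise A [sensor_noise_model()] supplying the bias vectors.
#' @param frame A [frame_convention()].
#' @return The [tracker_state()] at `s_t1$t`.
#' @export
integrate_step <- function(state, s_t, s_t1,
                           noise = sensor_noise_none(),
                           frame = frame_convention()) {
  dt <- s_t1$t - s_t$t
  if (!(dt > 0)) stop("non-monotone timestamps in integrate_step")
  if (dt > 0.1) stop("sample gap exceeds 0.1 s; resample the stream first")
  q <- state$q
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6) stop("state quaternion is not unit norm")

  g_down <- frame$gravity_vector
  Ba <- noise$accel_bias
  Bg <- noise$gyro_bias

  a_t_w <- quat_rotate(q, c(s_t$ax, s_t$ay, s_t$az) - Ba) + g_down
  wbar <- 0.5 * (c(s_t$gx, s_t$gy, s_t$gz) + c(s_t1$gx, s_t1$gy, s_t1$gz)) - Bg
  q1 <- quat_mul(q, quat_from_rotvec(wbar * dt))
  a_t1_w <- quat_rotate(q1, c(s_t1$ax, s_t1$ay, s_t1$az) - Ba) + g_down
  abar <- 0.5 * (a_t_w + a_t1_w)
  v1 <- state$v + abar * dt
  d1 <- state$d + state$v * dt + 0.5 * abar * dt^2
  tracker_state(q = q1, v = v1, d = d1, t = s_t1$t)
}

#' Integrate a whole IMU stream
#'
#' Folds [integrate_step()] over consecutive sample pairs. The output length
#' equals the input length; the first state is `initial` stamped with the
#' first sample time.
#'
#' @param stream An [imu_stream()] with at least 2 samples.
#' @param initial Initial [tracker_state()].
#' @param noise A [sensor_noise_model()].
#' @param frame A [frame_convention()].
#' @return List of [tracker_state()], one per sample.
#' @export
integrate_stream <- function(stream, initial = tracker_state(),
                             noise = sensor_noise_none(),
                             frame = frame_convention()) {
  n <- nrow(stream)
  if (n < 2) stop("integrate_stream needs at least 2 samples")
  tt <- stream$t
  if (any(diff(tt) <= 0)) stop("non-monotone timestamps")
  if (max(diff(tt)) > 0.1) stop("sample gap exceeds 0.1 s; resample the stream first")
  am <- cbind(stream$ax, stream$ay, stream$az)
  gm <- cbind(stream$gx, stream$gy, stream$gz)
  g_down <- frame$gravity_vector
  Ba <- noise$accel_bias
  Bg <- noise$gyro_bias

  q <- initial$q
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6) stop("initial quaternion is not unit norm")
  v <- initial$v
  d <- initial$d

  Q <- matrix(0, n, 4); V <- matrix(0, n, 3); D <- matrix(0, n, 3)
  Q[1, ] <- q; V[1, ] <- v; D[1, ] <- d
  a_w <- quat_rotate(q, am[1, ] - Ba) + g_down
  for (i in seq_len(n - 1)) {
    dt <- tt[i + 1] - tt[i]
    wbar <- 0.5 * (gm[i, ] + gm[i + 1, ]) - Bg
    q <- quat_mul(q, quat_from_rotvec(wbar * dt))
    a_w1 <- quat_rotate(q, am[i + 1, ] - Ba) + g_down
    abar <- 0.5 * (a_w + a_w1)
    d <- d + v * dt + 0.5 * abar * dt^2
    v <- v + abar * dt
    a_w <- a_w1
    Q[i + 1, ] <- q; V[i + 1, ] <- v; D[i + 1, ] <- d
  }
  lapply(seq_len(n), function(i) tracker_state(Q[i, ], V[i, ], D[i, ], tt[i]))
}

# Heading (rotation about the world down axis) of an orientation relative
# to a reference.
heading_of <- function(q, reference_q = quat_identity()) {
  rel <- quat_mul(q, quat_conj(reference_q))
  unname(quat_to_ypr(rel)["yaw"])
}

#' Heading drift compensation
#'
#' Pitch and roll are observable through the accelerometer; heading (rotation
#' about the gravity axis) is the unobservable drifting degree of freedom.
#' The heading deviation of the final state from `reference_q` is estimated
#' and the inverse heading rotation, scaled by
#' `cfg$drift_compensation_strength`, is applied with a linear ramp across
#' the sequence (zero correction at the first state, full scaled correction
#' at the last). Velocity and displacement are rotated consistently.
#'
#' @param states List of [tracker_state()].
#' @param reference_q Orientation captured at the most recent calibration.
#' @param cfg A [filter_config()].
#' @export
drift_compensate <- function(states, reference_q = quat_identity(),
                             cfg = filter_config()) {
  s <- cfg$drift_compensation_strength
  n <- length(states)
  if (s == 0 || n == 0) return(states)
  psi <- heading_of(states[[n]]$q, reference_q)
  if (n == 1) ramp <- 1 else ramp <- (seq_len(n) - 1) / (n - 1)
  lapply(seq_len(n), function(i) {
    ang <- -s * psi * ramp[i]
    corr <- quat_from_rotvec(c(0, ang, 0))
    st <- states[[i]]
    tracker_state(q = quat_mul(corr, st$q),
                  v = quat_rotate(corr, st$v),
                  d = quat_rotate(corr, st$d),
                  t = st$t)
  })
}
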