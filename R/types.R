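# Domain types: IMU streams, tracker states, sensor noise model, frame
# convention, filter configuration. Streams and state sequences are plain
# data.frames with a class attribute, in the style of base scientific R.

#' Tracker identifiers
#'
#' The six body-worn trackers: chest, waist, above each knee (femur-fixed)
#' and above each ankle (tibia-fixed).
#' @export
TRACKER_IDS <- c("chest", "waist", "l_knee", "l_ankle", "r_knee", "r_ankle")

GRAVITY_DEFAULT <- 9.81         # m/s^2; configurable via frame_convention()
ACCEL_FULL_SCALE_G <- 4         # +/- 4 g sensor range
GYRO_FULL_SCALE_DPS <- 250      # +/- 250 deg/s sensor range

#' World frame convention
#'
#' The world frame equals the body frame at upright calibration: Y points
#' down (along gravity), Z forward, X right (right-handed). A standing,
#' still subject therefore has identity tracker orientations.
#'
#' @param g Gravitational acceleration magnitude, m/s^2.
#' @return Object of class `frame_convention` with `gravity_vector`
#'   (m/s^2, world frame, pointing down) and named `world_axes`.
#' @export
frame_convention <- function(g = GRAVITY_DEFAULT) {
  stopifnot(is.numeric(g), abs(g - 9.81) <= 0.01)
  structure(list(
    gravity_vector = c(0, g, 0),
    world_axes = list(down = c(0, 1, 0), forward = c(0, 0, 1), right = c(1, 0, 0))
  ), class = "frame_convention")
}

# Zero-gravity variant used in closed-form kinematics tests.
#' @rdname frame_convention
#' @export
frame_convention_zero_g <- function() {
  structure(list(
    gravity_vector = c(0, 0, 0),
    world_axes = list(down = c(0, 1, 0), forward = c(0, 0, 1), right = c(1, 0, 0))
  ), class = "frame_convention")
}

#' Sensor noise model
#'
#' Noise spectral densities follow the BMI160-class budget: accelerometer
#' 300 ug/sqrt(Hz), gyroscope 0.007 deg/s/sqrt(Hz) at 100 Hz sampling.
#' Per-sample standard deviation = density * sqrt(sample_rate / 2).
#' Biases are constant vectors (no bias random walk).
#'
#' @param accel_noise_density ug/sqrt(Hz).
#' @param gyro_noise_density deg/s/sqrt(Hz).
#' @param accel_bias Length-3 accelerometer bias, m/s^2 (body frame).
#' @param gyro_bias Length-3 gyroscope bias, rad/s (body frame).
#' @param sample_rate Hz.
#' @export
sensor_noise_model <- function(accel_noise_density = 300,
                               gyro_noise_density = 0.007,
                               accel_bias = c(0, 0, 0),
                               gyro_bias = c(0, 0, 0),
                               sample_rate = 100) {
  stopifnot(accel_noise_density >= 0, gyro_noise_density >= 0, sample_rate > 0,
            length(accel_bias) == 3, length(gyro_bias) == 3)
  structure(list(
    accel_noise_density = accel_noise_density,
    gyro_noise_density = gyro_noise_density,
    accel_bias = as.numeric(accel_bias),
    gyro_bias = as.numeric(gyro_bias),
    sample_rate = sample_rate
  ), class = "sensor_noise_model")
}

#' Noise-free sensor model
#' @param sample_rate Hz.
#' @export
sensor_noise_none <- function(sample_rate = 100) {
  sensor_noise_model(0, 0, c(0, 0, 0), c(0, 0, 0), sample_rate)
}

#' Per-sample noise standard deviations in SI units
#'
#' @param noise A [sensor_noise_model()].
#' @param g Gravity used to convert ug to m/s^2.
#' @return Named numeric `c(accel=, gyro=)`: m/s^2 and rad/s.
#' @export
noise_sigma <- function(noise, g = GRAVITY_DEFAULT) {
  bw <- sqrt(noise$sample_rate / 2)
  c(accel = noise$accel_noise_density * 1e-6 * g * bw,
    gyro = noise$gyro_noise_density * pi / 180 * bw)
}

#' Filter configuration
#'
#' `filtering_strength` is the smoothing dial of the per-channel Kalman
#' filter (0 = pass-through, 1 = freeze at the first sample);
#' `drift_compensation_strength` scales the inverse heading rotation applied
#' against gyro heading drift. Defaults are the tuned operating point:
#' filtering 50%, drift compensation 20%.
#'
#' @param filtering_strength Fraction in `[0, 1]`.
#' @param drift_compensation_strength Fraction in `[0, 1]`.
#' @export
filter_config <- function(filtering_strength = 0.5,
                          drift_compensation_strength = 0.2) {
  stopifnot(filtering_strength >= 0, filtering_strength <= 1,
            drift_compensation_strength >= 0, drift_compensation_strength <= 1)
  structure(list(
    filtering_strength = filtering_strength,
    drift_compensation_strength = drift_compensation_strength
  ), class = "filter_config")
}

#' Construct an IMU stream
#'
#' A uniform time series of one tracker's samples: timestamp (s), body-frame
#' specific force (m/s^2; a motionless sensor reads the gravity reaction)
#' and body-frame angular velocity (rad/s).
#'
#' @param t Numeric timestamps, strictly increasing (s).
#' @param accel n x 3 matrix, m/s^2.
#' @param gyro n x 3 matrix, rad/s.
#' @param tracker_id One of [TRACKER_IDS] (other ids allowed for synthetic
#'   tests, with a warning suppressible via `strict = FALSE`).
#' @param strict Validate ranges and ids.
#' @return data.frame of class `imu_stream` with columns
#'   `t, ax, ay, az, gx, gy, gz, tracker_id`.
#' @export
imu_stream <- function(t, accel, gyro, tracker_id, strict = TRUE) {
  accel <- matrix(as.numeric(accel), ncol = 3)
  gyro <- matrix(as.numeric(gyro), ncol = 3)
  stopifnot(length(t) == nrow(accel), nrow(accel) == nrow(gyro))
  x <- data.frame(t = as.numeric(t),
                  ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                  gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                  tracker_id = as.character(tracker_id))
  class(x) <- c("imu_stream", "data.frame")
  if (strict) validate_imu_stream(x)
  x
}

#' Validate an IMU stream
#'
#' Checks strictly increasing timestamps and warns when samples exceed the
#' sensor full scale (+/-4 g acceleration, +/-250 deg/s angular velocity).
#'
#' @param x An `imu_stream`.
#' @param g Gravity for the g-to-m/s^2 conversion.
#' @export
validate_imu_stream <- function(x, g = GRAVITY_DEFAULT) {
  stopifnot(is.data.frame(x),
            all(c("t", "ax", "ay", "az", "gx", "gy", "gz") %in% names(x)))
  if (nrow(x) > 1 && any(diff(x$t) <= 0)) {
    stop("imu_stream timestamps must be strictly increasing")
  }
  amax <- max(abs(as.matrix(x[, c("ax", "ay", "az")])))
  gmax <- max(abs(as.matrix(x[, c("gx", "gy", "gz")])))
  if (amax > ACCEL_FULL_SCALE_G * g) {
    warning(sprintf("accelerometer saturation: |a| = %.2f m/s^2 exceeds %.1f g full scale",
                    amax, ACCEL_FULL_SCALE_G))
  }
  if (gmax > GYRO_FULL_SCALE_DPS * pi / 180) {
    warning(sprintf("gyroscope saturation: |w| = %.1f deg/s exceeds %d deg/s full scale",
                    gmax * 180 / pi, GYRO_FULL_SCALE_DPS))
  }
  invisible(x)
}

#' Tracker state
#'
#' Orientation (unit quaternion, body-to-world), velocity and displacement
#' of one tracker in the world frame.
#'
#' @param q Unit quaternion.
#' @param v Length-3 velocity, m/s.
#' @param d Length-3 displacement, m.
#' @param t Timestamp, s.
#' @export
tracker_state <- function(q = quat_identity(), v = c(0, 0, 0), d = c(0, 0, 0), t = 0) {
  q <- as.numeric(q)
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6) stop("tracker_state requires a unit quaternion")
  stopifnot(all(is.finite(c(q, v, d, t))))
  structure(list(q = q, v = as.numeric(v), d = as.numeric(d), t = as.numeric(t)),
            class = "tracker_state")
}

#' Convert a sequence of tracker states to a data.frame
#'
#' @param states List of [tracker_state()] objects.
#' @param tracker_id Optional id column.
#' @return data.frame `t,qw,qx,qy,qz,vx,vy,vz,dx,dy,dz[,tracker_id]`.
#' @export
states_to_df <- function(states, tracker_id = NULL) {
  m <- t(vapply(states, function(s) c(s$t, quat_canonical(s$q), s$v, s$d),
                numeric(11)))
  df <- as.data.frame(m)
  names(df) <- c("t", "qw", "qx", "qy", "qz", "vx", "vy", "vz", "dx", "dy", "dz")
  if (!is.null(tracker_id)) df$tracker_id <- tracker_id
  df
}

#' @rdname states_to_df
#' @param df A data.frame produced by [states_to_df()].
#' @export
df_to_states <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    tracker_state(q = c(df$qw[i], df$qx[i], df$qy[i], df$qz[i]),
                  v = c(df$vx[i], df$vy[i], df$vz[i]),
                  d = c(df$dx[i], df$dy[i], df$dz[i]),
                  t = df$t[i])
  })
}

# ---- Stream I/O ------------------------------------------------------------

#' Read / write IMU streams as CSV
#'
#' CSV dialect: header `t,ax,ay,az,gx,gy,gz,tracker_id`; `t` in seconds
#' (6 decimals), acceleration in m/s^2, angular velocity in rad/s.
#'
#' @param x An `imu_stream`.
#' @param path File path.
#' @export
write_imu_csv <- function(x, path) {
  out <- x
  out$t <- sprintf("%.6f", out$t)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  imu_stream(df$t, as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("gx", "gy", "gz")]), df$tracker_id,
             strict = FALSE)
}

#' Read / write IMU streams as JSON lines
#'
#' One sample per line, keys `t, ax, ay, az, gx, gy, gz, tracker_id`.
#'
#' @param x An `imu_stream`.
#' @param path File path.
#' @export
write_imu_jsonl <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(jsonlite::toJSON(as.list(x[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_imu_jsonl
#' @export
read_imu_jsonl <- function(path) {
  rows <- lapply(readLines(path), function(l) as.data.frame(jsonlite::fromJSON(l)))
  df <- do.call(rbind, rows)
  imu_stream(df$t, as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("gx", "gy", "gz")]), df$tracker_id,
             strict = FALSE)
}

#' Write a tracker-state sequence as CSV
#' @param df data.frame from [states_to_df()].
#' @param path File path.
#' @export
write_states_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Resample an IMU stream to a uniform rate
#'
#' Streams whose timestamp jitter exceeds 10% of the nominal interval are
#' linearly interpolated onto a uniform grid; otherwise returned unchanged.
#'
#' @param x An `imu_stream`.
#' @param rate Target rate, Hz.
#' @export
resample_stream <- function(x, rate = 100) {
  dt <- diff(x$t)
  if (length(dt) == 0) return(x)
  nominal <- 1 / rate
  if (max(abs(dt - nominal)) <= 0.1 * nominal) return(x)
  tg <- seq(x$t[1], x$t[nrow(x)], by = nominal)
  cols <- c("ax", "ay", "az", "gx", "gy", "gz")
  m <- vapply(cols, function(cl) stats::approx(x$t, x[[cl]], xout = tg)$y,
              numeric(length(tg)))
  imu_stream(tg, m[, 1:3], m[, 4:6], x$tracker_id[1], strict = FALSE)
}
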