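# Quaternion primitives.
#
# Convention used throughout the package: Hamilton product, scalar-first
# c(w, x, y, z), unit norm. A quaternion q rotates body-frame vectors into
# the world frame when applied as q v q* (see quat_rotate). q and -q denote
# the same orientation; serialization canonicalizes to w >= 0.

#' Construct a quaternion
#'
#' Quaternions are plain numeric vectors `c(w, x, y, z)` (scalar first,
#' Hamilton convention). They rotate body-frame vectors into the world frame
#' when applied as `q v q*`.
#'
#' @param w,x,y,z Components.
#' @return Numeric vector of length 4 with unit norm.
#' @export
quat <- function(w = 1, x = 0, y = 0, z = 0) {
  quat_normalize(c(w, x, y, z))
}

#' Identity quaternion
#' @return `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Normalize a quaternion to unit norm
#' @param q Quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (!is.finite(n) || n == 0) stop("cannot normalize zero or non-finite quaternion")
  q / n
}

#' Canonicalize the double cover (force w >= 0)
#' @param q Quaternion.
#' @export
quat_canonical <- function(q) {
  if (q[1] < 0) -q else q
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q Quaternion.
#' @export
quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Hamilton product of two quaternions
#'
#' @param a,b Unit quaternions.
#' @return `a %*% b` (apply `b` first when rotating body-to-world), renormalized.
#' @export
quat_mul <- function(a, b) {
  q <- c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
  quat_normalize(q)
}

#' Exponential map: rotation vector to quaternion
#'
#' `v` is an axis-angle rotation vector in radians (angle = `|v|`). For tiny
#' angles the first-order expansion `(1, v/2)` is used and renormalized.
#'
#' @param v Numeric length-3 rotation vector (rad).
#' @export
quat_from_rotvec <- function(v) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  theta <- sqrt(sum(v * v))
  if (theta < 1e-12) {
    quat_normalize(c(1, v / 2))
  } else {
    c(cos(theta / 2), sin(theta / 2) * v / theta)
  }
}

#' Log map: quaternion to rotation vector
#'
#' Inverse of [quat_from_rotvec()] for rotation angles below pi.
#'
#' @param q Unit quaternion.
#' @return Rotation vector (rad).
#' @export
quat_to_rotvec <- function(q) {
  q <- quat_canonical(quat_normalize(q))
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) {
    2 * q[2:4]  # first order: q ~ (1, v/2)
  } else {
    theta <- 2 * atan2(s, q[1])
    theta * q[2:4] / s
  }
}

#' Rotate a vector by a quaternion
#'
#' Applies `q v q*`: body-frame to world-frame for orientation quaternions.
#' Norm-preserving.
#'
#' @param q Unit quaternion.
#' @param v Numeric length-3 vector.
#' @export
quat_rotate <- function(q, v) {
  u <- q[2:4]
  t <- 2 * c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  v + q[1] * t + c(
    u[2] * t[3] - u[3] * t[2],
    u[3] * t[1] - u[1] * t[3],
    u[1] * t[2] - u[2] * t[1]
  )
}

#' Quaternion from axis and angle
#' @param axis Length-3 axis (need not be unit).
#' @param angle Angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  stopifnot(n > 0)
  quat_from_rotvec(axis / n * angle)
}

#' Rotation matrix of a quaternion
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix `R` with `R %*% v == quat_rotate(q, v)`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Angular distance between two orientations
#' @param a,b Unit quaternions.
#' @return Angle in radians in `[0, pi]`, double-cover aware.
#' @export
quat_angle <- function(a, b = quat_identity()) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d))
}

#' Intrinsic yaw-pitch-roll to quaternion
#'
#' Composition `qY(yaw) * qX(pitch) * qZ(roll)` about the world axes
#' Y (down), X (right), Z (forward) — intrinsic yaw, then pitch, then roll.
#' With the Y-down frame, positive pitch about X takes the down axis toward
#' forward (leg flexion positive).
#'
#' @param yaw,pitch,roll Angles in radians.
#' @export
ypr_to_quat <- function(yaw, pitch, roll = 0) {
  qy <- c(cos(yaw / 2), 0, sin(yaw / 2), 0)
  qx <- c(cos(pitch / 2), sin(pitch / 2), 0, 0)
  qz <- c(cos(roll / 2), 0, 0, sin(roll / 2))
  quat_mul(quat_mul(qy, qx), qz)
}

#' Quaternion to intrinsic yaw-pitch-roll
#'
#' Inverse of [ypr_to_quat()]. Near gimbal lock (`|pitch| -> pi/2`) roll is
#' set to 0 and yaw absorbs the in-plane rotation.
#'
#' @param q Unit quaternion.
#' @return Named numeric `c(yaw=, pitch=, roll=)` in radians.
#' @export
quat_to_ypr <- function(q) {
  R <- quat_to_matrix(quat_normalize(q))
  s <- -R[2, 3]
  s <- max(-1, min(1, s))
  if (abs(s) > 1 - 1e-9) {
    pitch <- asin(s)
    yaw <- atan2(-R[3, 1], R[1, 1])
    roll <- 0
  } else {
    pitch <- asin(s)
    yaw <- atan2(R[1, 3], R[3, 3])
    roll <- atan2(R[2, 1], R[2, 2])
  }
  c(yaw = yaw, pitch = pitch, roll = roll)
}
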