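# Scalar Kalman filtering of IMU channels.
#
# Each of the six raw channels (ax..gz) is smoothed independently with a
# scalar random-walk Kalman filter (A = 1, B = 0, H = 1). The user-facing
# "filtering strength" s maps to the steady-state gain K = 1 - s; the
# process/measurement variances reproducing that gain are recovered from the
# discrete Riccati fixed point (see strength_to_qr).

#' Scalar Kalman channel
#'
#' State of one scalar Kalman filter: estimate `x`, variance `p`, model
#' scalars `a` (state transition), `b`/`u` (control), `h` (observation),
#' `q` (process noise variance), `r` (measurement noise variance).
#'
#' @param x,p,a,b,u,h,q,r Scalars; `p, q, r >= 0`.
#' @export
kalman_channel <- function(x = 0, p = 1, a = 1, b = 0, u = 0, h = 1, q = 0, r = 0) {
  stopifnot(p >= 0, q >= 0, r >= 0)
  structure(list(x = x, p = p, a = a, b = b, u = u, h = h, q = q, r = r,
                 k = NA_real_),
            class = "kalman_channel")
}

#' Kalman prediction step
#'
#' Prior estimate `x- = a x + b u`; prior variance `p- = a p a + q`.
#'
#' @param ch A [kalman_channel()].
#' @export
kalman_predict <- function(ch) {
  ch$x <- ch$a * ch$x + ch$b * ch$u
  ch$p <- ch$a * ch$p * ch$a + ch$q
  ch
}

#' Kalman correction step
#'
#' Gain `k = p- h / (h p- h + r)`; posterior `x = x- + k (z - h x-)`;
#' variance `p = (1 - h k) p-`. Must follow [kalman_predict()].
#'
#' @param ch A [kalman_channel()] holding the prior.
#' @param z Measurement.
#' @export
kalman_update <- function(ch, z) {
  denom <- ch$h * ch$p * ch$h + ch$r
  if (denom == 0) stop("degenerate Kalman gain: h^2 p + r = 0")
  k <- ch$p * ch$h / denom
  ch$x <- ch$x + k * (z - ch$h * ch$x)
  ch$p <- (1 - ch$h * k) * ch$p
  ch$k <- k
  ch
}

#' Map filtering strength to random-walk noise variances
#'
#' For the random-walk channel model the steady-state gain is
#' `K = M / (M + r)` with prior variance `M = P + q` and posterior variance
#' `P = (-q + sqrt(q^2 + 4 q r)) / 2` (Riccati fixed point). Fixing the
#' scale `M = 1` and the gain `K = 1 - s` gives `q = K`, `r = (1 - K)/K`.
#' `s = 0` yields `r = 0` (gain 1: pass-through); `s = 1` yields `q = 0`,
#' `r = Inf` (gain 0: output frozen at the initial estimate).
#'
#' @param strength Filtering strength in `[0, 1]`.
#' @return Named list `q`, `r`, `gain`, `p_post` (steady-state posterior
#'   variance).
#' @export
strength_to_qr <- function(strength) {
  stopifnot(strength >= 0, strength <= 1)
  K <- 1 - strength
  if (K == 0) {
    list(q = 0, r = Inf, gain = 0, p_post = 0)
  } else {
    list(q = K, r = strength / K, gain = K, p_post = strength)
  }
}

#' Riccati fixed point of the random-walk filter
#'
#' Steady-state posterior variance `p = (-q + sqrt(q^2 + 4 q r)) / 2`.
#'
#' @param q Process noise variance.
#' @param r Measurement noise variance.
#' @export
riccati_fixed_point <- function(q, r) {
  (-q + sqrt(q^2 + 4 * q * r)) / 2
}

# Run the steady-state scalar filter over one channel. Initialized at the
# fixed point (x0 = first sample, p0 = posterior variance), the gain is the
# constant K = 1 - s and the recursion collapses to the exponential moving
# average y_k = s y_{k-1} + (1 - s) z_k. Equivalence with the explicit
# predict/update recursion is asserted in the test suite.
filter_channel <- function(z, strength) {
  if (strength == 0) return(z)
  if (strength == 1) return(rep(z[1], length(z)))
  K <- 1 - strength
  y <- numeric(length(z))
  y[1] <- z[1]
  for (i in seq_along(z)[-1]) y[i] <- strength * y[i - 1] + K * z[i]
  y
}

#' Kalman-filter all six channels of an IMU stream
#'
#' Applies the random-walk scalar Kalman filter independently to each of
#' `ax..gz`. Output has the same length and timestamps. Strength 0 is the
#' identity transform.
#'
#' @param stream An [imu_stream()].
#' @param cfg A [filter_config()]; `cfg$filtering_strength` is used.
#' @export
filter_stream <- function(stream, cfg = filter_config()) {
  if (nrow(stream) == 0) stop("cannot filter an empty stream")
  s <- cfg$filtering_strength
  out <- stream
  for (cl in c("ax", "ay", "az", "gx", "gy", "gz")) {
    out[[cl]] <- filter_channel(stream[[cl]], s)
  }
  out
}
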