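make_stream <- function(n, accel, gyro, dt = 0.01, id = "chest") {
  imu_stream(seq(0, by = dt, length.out = n),
             matrix(rep(accel, each = n), n, 3),
             matrix(rep(gyro, each = n), n, 3), id, strict = FALSE)
}

test_that("statics: a motionless tracker at any orientation stays put", {
  set.seed(31)
  frame <- frame_convention()
  for (rep in 1:5) {
    q0 <- random_unit_quat()
    # specific force of a still sensor: gravity reaction rotated into body frame
    fb <- quat_rotate(quat_conj(q0), -frame$gravity_vector)
    stream <- make_stream(101, fb, c(0, 0, 0))
    states <- integrate_stream(stream, tracker_state(q = q0), frame = frame)
    fin <- states[[101]]
    expect_equal(quat_angle(fin$q, q0), 0, tolerance = 1e-9)
    expect_equal(fin$v, c(0, 0, 0), tolerance = 1e-9)
    expect_equal(fin$d, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("inertial coasting and closed-form kinematics", {
  zg <- frame_convention_zero_g()
  # coasting: no force, initial velocity (1,0,0), one step of 0.01 s
  stream <- make_stream(2, c(0, 0, 0), c(0, 0, 0))
  st <- integrate_step(tracker_state(v = c(1, 0, 0)), stream[1, ], stream[2, ],
                       frame = zg)
  expect_equal(st$d, c(0.01, 0, 0), tolerance = 1e-12)

  # constant rotation pi/2 rad/s about Z for 1 s -> 90 degrees about Z
  stream <- make_stream(101, c(0, 0, 0), c(0, 0, pi / 2))
  states <- integrate_stream(stream, tracker_state(), frame = zg)
  expect_equal(quat_angle(states[[101]]$q, quat_from_rotvec(c(0, 0, pi / 2))),
               0, tolerance = 1e-6)

  # constant world acceleration (1,0,0) from rest for 1 s -> D = (0.5,0,0)
  stream <- make_stream(101, c(1, 0, 0), c(0, 0, 0))
  states <- integrate_stream(stream, tracker_state(), frame = zg)
  expect_equal(states[[101]]$d, c(0.5, 0, 0), tolerance = 1e-3)
  expect_equal(states[[101]]$v, c(1, 0, 0), tolerance = 1e-6)
})

test_that("integrate_stream folds integrate_step and validates input", {
  stream <- make_stream(2, c(0.3, -0.1, 0.2), c(0.05, 0.1, -0.04))
  zg <- frame_convention_zero_g()
  states <- integrate_stream(stream, tracker_state(), frame = zg)
  expect_length(states, 2)
  direct <- integrate_step(tracker_state(), stream[1, ], stream[2, ], frame = zg)
  expect_equal(states[[2]]$q, direct$q)
  expect_equal(states[[2]]$d, direct$d)

  expect_error(integrate_stream(stream[1, , drop = FALSE], tracker_state()),
               "at least 2")
  bad <- stream; bad$t <- c(0.02, 0.01)
  expect_error(integrate_stream(bad, tracker_state()), "monotone")
  gap <- stream; gap$t <- c(0, 0.5)
  expect_error(integrate_stream(gap, tracker_state()), "0.1 s")
  expect_error(integrate_step(tracker_state(), stream[2, ], stream[1, ]),
               "monotone")
})

test_that("a known constant gyro bias cancels exactly", {
  set.seed(32)
  zg <- frame_convention_zero_g()
  n <- 200
  gyro <- matrix(stats::rnorm(3 * n, sd = 0.3), n, 3)
  t <- seq(0, by = 0.01, length.out = n)
  clean <- imu_stream(t, matrix(0, n, 3), gyro, "chest", strict = FALSE)
  bg <- c(0.02, -0.05, 0.01)
  biased <- imu_stream(t, matrix(0, n, 3), sweep(gyro, 2, bg, `+`), "chest",
                       strict = FALSE)
  s0 <- integrate_stream(clean, tracker_state(), frame = zg)
  s1 <- integrate_stream(biased, tracker_state(),
                         noise = sensor_noise_model(0, 0, gyro_bias = bg),
                         frame = zg)
  expect_equal(s1[[n]]$q, s0[[n]]$q, tolerance = 1e-12)
})

test_that("quaternion norm is preserved over long integrations", {
  set.seed(33)
  n <- 5000
  stream <- imu_stream(seq(0, by = 0.01, length.out = n),
                       matrix(stats::rnorm(3 * n), n, 3),
                       matrix(stats::rnorm(3 * n, sd = 2), n, 3), "chest",
                       strict = FALSE)
  states <- integrate_stream(stream, tracker_state(),
                             frame = frame_convention_zero_g())
  norms <- vapply(states[seq(1, n, 250)], function(s) sqrt(sum(s$q^2)), numeric(1))
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-9)
})

test_that("drift compensation removes the scaled heading error", {
  # linear 10-degree heading drift about the down axis
  n <- 101
  psi <- seq(0, 10 * pi / 180, length.out = n)
  states <- lapply(seq_len(n), function(i) {
    tracker_state(q = quat_from_rotvec(c(0, psi[i], 0)), t = (i - 1) * 0.01)
  })
  ref <- quat_identity()

  same <- drift_compensate(states, ref, filter_config(drift_compensation_strength = 0))
  expect_equal(same[[n]]$q, states[[n]]$q)

  full <- drift_compensate(states, ref, filter_config(drift_compensation_strength = 1))
  expect_equal(imuposture:::heading_of(full[[n]]$q, ref) * 180 / pi, 0,
               tolerance = 1e-6)

  part <- drift_compensate(states, ref, filter_config(drift_compensation_strength = 0.2))
  expect_equal(imuposture:::heading_of(part[[n]]$q, ref) * 180 / pi, 8,
               tolerance = 1e-6)
  # ramp: first state is untouched
  expect_equal(part[[1]]$q, states[[1]]$q)
})
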