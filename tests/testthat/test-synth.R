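sk <- skeleton_from_height(1580)

test_that("generated trajectories stay inside the shrunk taxonomy ranges", {
  for (lab in c(1L, 3L, 5L)) {
    tr <- generate_posture_trajectory(lab, 10, seed = 100 + lab)
    r <- POSTURE_RANGES[lab, ]
    shr <- function(lo, hi) c(lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))
    tor <- shr(r["torso_lo"], r["torso_hi"])
    hip <- shr(r["hip_lo"], r["hip_hi"])
    kne <- shr(r["knee_lo"], r["knee_hi"])
    expect_true(all(tr$bends[, "torso"] >= tor[1] - 1e-9 &
                      tr$bends[, "torso"] <= tor[2] + 1e-9))
    expect_true(all(tr$bends[, c("hip_l", "hip_r")] >= hip[1] - 1e-9 &
                      tr$bends[, c("hip_l", "hip_r")] <= hip[2] + 1e-9))
    expect_true(all(tr$bends[, c("knee_l", "knee_r")] >= kne[1] - 1e-9 &
                      tr$bends[, c("knee_l", "knee_r")] <= kne[2] + 1e-9))
  }
  expect_error(generate_posture_trajectory(9, 1), "invalid")
})

test_that("trajectories are deterministic and classify to their own label", {
  a <- generate_posture_trajectory(4, 5, seed = 77)
  b <- generate_posture_trajectory(4, 5, seed = 77)
  expect_identical(a, b)
  for (lab in 1:7) {
    tr <- generate_posture_trajectory(lab, 5, seed = 200 + lab)
    labs <- classify_by_rules(tr$bends[, "torso"],
                              pmax(tr$bends[, "hip_l"], tr$bends[, "hip_r"]),
                              pmax(tr$bends[, "knee_l"], tr$bends[, "knee_r"]))
    expect_gte(mean(labs == lab), 0.99)
  }
})

test_that("build_session concatenates tasks with excluded transitions", {
  sc <- session_script(c(2L, 6L), c(10000, 8000))
  tr <- build_session(sc, seed = 5)
  r <- rle(ifelse(is.na(tr$labels), -1L, tr$labels))
  expect_equal(r$values, c(2L, -1L, 6L))     # labels occur in script order
  expect_equal(r$lengths[c(1, 3)], c(1000, 800))  # full scripted durations
  expect_equal(r$lengths[2], 200)            # 2 s transition at 100 Hz

  # single task: one labeled block, no transitions
  one <- build_session(session_script(3L, 10000), seed = 5)
  expect_equal(length(one$labels), 1000)
  expect_true(all(one$labels == 3L))

  # preparation/break rows are excluded standing-like motion
  full <- table3_script(scale = 1 / 50)
  expect_true(is.na(full$tasks$label[1]))
  expect_equal(sum(full$tasks$duration_ms), 863350 * 1 / 50 + 60000 / 50)
})

test_that("labeled proportions match the scripted durations within 2%", {
  tr <- build_session(table3_script(scale = 1 / 20), seed = 9)
  dur <- table3_script(scale = 1 / 20)$tasks
  lab_ms <- dur$duration_ms[!is.na(dur$label)]
  got <- table(tr$labels) / sum(!is.na(tr$labels))
  want <- lab_ms / sum(lab_ms)
  expect_true(all(abs(as.numeric(got) - want) < 0.02))
})

test_that("forward sensor model: statics, noise scaling, saturation guard", {
  # motionless standing, zero noise -> zero gyro and zero drift
  tr <- constant_trace(c(0, 0, 0, 0, 0), n = 200, label = 1L)
  sim <- imu_from_motion(tr, sk, seed = 3)
  gy <- as.matrix(sim$streams$chest[, c("gx", "gy", "gz")])
  expect_equal(max(abs(gy)), 0, tolerance = 1e-9)
  init <- tracker_state(q = quat_identity(), d = c(
    sim$truth$chest$px[1], sim$truth$chest$py[1], sim$truth$chest$pz[1]))
  states <- integrate_stream(sim$streams$chest, init)
  drift <- sqrt(sum((states[[200]]$d - states[[1]]$d)^2))
  expect_equal(drift, 0, tolerance = 1e-9)

  # density-to-sigma conversion: 0.007 deg/s/sqrt(Hz) at 100 Hz
  sig <- noise_sigma(sensor_noise_model())
  expect_equal(unname(sig["gyro"]) * 180 / pi, 0.007 * sqrt(50), tolerance = 1e-12)
  expect_equal(unname(sig["accel"]), 300e-6 * 9.81 * sqrt(50), tolerance = 1e-12)

  # empirical noise sd matches the configured density
  simn <- imu_from_motion(tr, sk, noise = sensor_noise_model(), seed = 4)
  res <- as.matrix(simn$streams$waist[, c("gx", "gy", "gz")])
  expect_equal(stats::sd(res), unname(sig["gyro"]), tolerance = 0.1)

  expect_error(imu_from_motion(constant_trace(c(0, 0, 0, 0, 0), n = 2), sk),
               "3 frames")
  # full-scale violation warns
  big <- imu_stream(c(0, 0.01), matrix(60, 2, 3), matrix(0, 2, 3), "chest",
                    strict = FALSE)
  expect_warning(validate_imu_stream(big), "saturation")
})

test_that("round trip: sensor model then strapdown recovers the trajectory", {
  tr <- generate_posture_trajectory(5, 10, seed = 55)  # squat cycling, 10 s
  sim <- imu_from_motion(tr, sk, seed = 56)            # noiseless
  for (id in c("chest", "l_knee")) {
    tru <- sim$truth[[id]]
    init <- tracker_state(q = c(tru$qw[1], tru$qx[1], tru$qy[1], tru$qz[1]),
                          v = c(tru$vx[1], tru$vy[1], tru$vz[1]),
                          d = c(tru$px[1], tru$py[1], tru$pz[1]), t = tru$t[1])
    states <- integrate_stream(sim$streams[[id]], init)
    qerr <- vapply(seq(1, 1000, 25), function(i) {
      quat_angle(states[[i]]$q, c(tru$qw[i], tru$qx[i], tru$qy[i], tru$qz[i]))
    }, numeric(1)) * 180 / pi
    expect_lt(max(qerr), 0.5)                     # orientation over 10 s
    i2 <- 200
    derr <- sqrt(sum((states[[i2]]$d - c(tru$px[i2], tru$py[i2], tru$pz[i2]))^2))
    expect_lt(derr, 0.05)                         # displacement at 2 s
  }
})

test_that("round trip survives sensor noise with drift compensation on", {
  tr <- generate_posture_trajectory(2, 10, seed = 60)
  sim <- imu_from_motion(tr, sk, noise = sensor_noise_model(), seed = 61)
  tru <- sim$truth$r_knee
  init <- tracker_state(q = c(tru$qw[1], tru$qx[1], tru$qy[1], tru$qz[1]),
                        v = c(tru$vx[1], tru$vy[1], tru$vz[1]),
                        d = c(tru$px[1], tru$py[1], tru$pz[1]), t = tru$t[1])
  states <- integrate_stream(sim$streams$r_knee, init)
  states <- drift_compensate(states, init$q, filter_config())
  qerr <- vapply(seq(1, 1000, 50), function(i) {
    quat_angle(states[[i]]$q, c(tru$qw[i], tru$qx[i], tru$qy[i], tru$qz[i]))
  }, numeric(1)) * 180 / pi
  expect_lt(max(qerr), 3)
})

test_that("stream serialization round-trips through CSV and JSONL", {
  tr <- constant_trace(c(10, 20, 20, 5, 5), n = 5, label = 2L)
  sim <- imu_from_motion(tr, sk, noise = sensor_noise_model(), seed = 8)
  s <- sim$streams$l_ankle
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".jsonl")
  write_imu_csv(s, p1)
  back <- read_imu_csv(p1)
  expect_equal(back$ax, s$ax, tolerance = 1e-9)
  expect_equal(back$t, s$t, tolerance = 1e-6)
  write_imu_jsonl(s, p2)
  backj <- read_imu_jsonl(p2)
  expect_equal(backj$gz, s$gz, tolerance = 1e-9)
})
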