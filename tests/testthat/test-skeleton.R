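sk <- skeleton_from_height(1580)

test_that("segment lengths scale with stature", {
  expect_equal(unname(sk$segment_lengths[["femur"]]), 1580 * 0.245)  # 387.1 mm
  expect_true(all(sk$segment_lengths > 0))
  sk2 <- skeleton_from_height(2000)
  expect_equal(unname(sk2$segment_lengths) / unname(sk$segment_lengths),
               rep(2000 / 1580, length(sk$segment_lengths)))
  expect_error(skeleton_from_height(900), "height")
  expect_error(skeleton_from_height(3000), "height")
})

test_that("forward kinematics: neutral pose geometry", {
  fk <- forward_kinematics(sk, neutral_angles())
  expect_equal(unname(fk$pos["pelvis", ]), c(0, 0, 0))
  # ankle sits femur + tibia below the hip (Y down)
  expect_equal(fk$pos["l_ankle", "y"] - fk$pos["l_hip", "y"],
               unname(sk$segment_lengths[["femur"]] + sk$segment_lengths[["tibia"]]))
  # chest is above the pelvis
  expect_equal(unname(fk$pos["thoracic", "y"]), -0.288 * 1580)
})

test_that("forward kinematics: 90-degree knee bend displaces the ankle horizontally", {
  a <- neutral_angles()
  a["l_knee", "pitch"] <- -pi / 2   # knee flexion folds the shank backward
  fk <- forward_kinematics(sk, a)
  rel <- fk$pos["l_ankle", ] - fk$pos["l_knee", ]
  expect_equal(unname(rel["y"]), 0, tolerance = 1e-6)
  expect_equal(sqrt(sum(rel^2)), unname(sk$segment_lengths[["tibia"]]),
               tolerance = 1e-6)
})

test_that("forward kinematics: left/right mirror symmetry", {
  a <- neutral_angles()
  a["l_hip", "pitch"] <- 0.8; a["l_knee", "pitch"] <- -0.5
  b <- neutral_angles()
  b["r_hip", "pitch"] <- 0.8; b["r_knee", "pitch"] <- -0.5
  fa <- forward_kinematics(sk, a); fb <- forward_kinematics(sk, b)
  mir <- fb$pos["r_ankle", ] * c(-1, 1, 1)
  expect_equal(unname(fa$pos["l_ankle", ]), unname(mir), tolerance = 1e-9)
})

test_that("forward kinematics: bone lengths are conserved under random postures", {
  set.seed(41)
  for (i in 1:200) {
    a <- neutral_angles()
    for (j in JOINT_ORDER) {
      for (comp in imuposture:::JOINT_DOF[[j]]) a[j, comp] <- stats::runif(1, -1.2, 1.2)
    }
    fk <- forward_kinematics(sk, a)
    for (j in setdiff(JOINT_ORDER, "pelvis")) {
      par <- imuposture:::JOINT_PARENT[[j]]
      d <- sqrt(sum((fk$pos[j, ] - fk$pos[par, ])^2))
      expect_equal(d, sqrt(sum(sk$offsets[j, ]^2)), tolerance = 1e-6)
    }
  }
  expect_error(forward_kinematics(sk, neutral_angles() * NaN), "finite")
  bad <- neutral_angles(); bad["l_knee", "yaw"] <- 0.3
  expect_error(forward_kinematics(sk, bad), "degrees of freedom")
})

test_that("two-pose calibration recovers mounting rotations", {
  # ski pose used throughout: torso forward, hips and knees flexed
  ski <- neutral_angles()
  ski["lumbar", "pitch"] <- ski["thoracic", "pitch"] <- -15 * pi / 180
  for (s in c("l", "r")) {
    ski[paste0(s, "_hip"), "pitch"] <- 45 * pi / 180
    ski[paste0(s, "_knee"), "pitch"] <- -50 * pi / 180
  }
  up_st <- states_from_angles(sk, neutral_angles())
  ski_st <- states_from_angles(sk, ski)

  # identity mounting
  cal <- calibrate(lapply(up_st, `[[`, "q"), lapply(ski_st, `[[`, "q"))
  for (id in TRACKER_IDS) {
    expect_equal(cal$mounting_q[[id]], quat_identity(), tolerance = 1e-9)
  }

  # one tracker rotated 180 degrees about its Y at mount time
  m_true <- quat_from_rotvec(c(0, pi, 0))
  up2 <- lapply(up_st, `[[`, "q")
  ski2 <- lapply(ski_st, `[[`, "q")
  # sensor = segment x mounting^-1
  up2$chest <- quat_mul(up2$chest, quat_conj(m_true))
  ski2$chest <- quat_mul(ski2$chest, quat_conj(m_true))
  cal2 <- calibrate(up2, ski2)
  expect_equal(quat_angle(cal2$mounting_q$chest, m_true), 0, tolerance = 1e-9)

  # flipped thigh tracker in the ski pose is detected and named
  ski3 <- lapply(ski_st, `[[`, "q")
  ski3$r_knee <- quat_mul(quat_from_rotvec(c(pi, 0, 0)), ski3$r_knee)
  expect_error(calibrate(lapply(up_st, `[[`, "q"), ski3), "r_knee")
  expect_error(calibrate(list(chest = quat_identity()),
                         lapply(ski_st, `[[`, "q")), "misses trackers")
})

test_that("states_to_posture recovers constructed joint configurations", {
  cal <- identity_calibration()
  # all trackers identity -> standing frame, label 1
  st <- states_from_angles(sk, neutral_angles())
  pf <- states_to_posture(st, cal, sk)
  expect_equal(max(abs(pf$joint_angles)), 0, tolerance = 1e-9)
  expect_equal(unname(pf$bends), rep(0, 5), tolerance = 1e-9)
  expect_equal(pf$label, 1L)

  # chest pitched 30 degrees forward -> torso bend 30
  a <- neutral_angles()
  a["lumbar", "pitch"] <- a["thoracic", "pitch"] <- -15 * pi / 180
  pf <- states_to_posture(states_from_angles(sk, a), cal, sk)
  expect_equal(unname(pf$bends[["torso"]]), 30, tolerance = 1e-6)

  # thighs pitched 80, shanks pitched -40 -> knee bend 120
  a <- neutral_angles()
  for (s in c("l", "r")) {
    a[paste0(s, "_hip"), "pitch"] <- 80 * pi / 180
    a[paste0(s, "_knee"), "pitch"] <- -120 * pi / 180  # shank at 80 - 120 = -40
  }
  pf <- states_to_posture(states_from_angles(sk, a), cal, sk)
  expect_equal(unname(pf$bends[["knee_l"]]), 120, tolerance = 1e-6)
  expect_equal(unname(pf$bends[["hip_l"]]), 80, tolerance = 1e-6)

  # recovered angles reproduce the generating rotations (module inverse)
  set.seed(42)
  tr <- generate_posture_trajectory(4, 1, seed = 7)
  ang <- tr$angles[30, , ]
  pf <- states_to_posture(states_from_angles(sk, ang), cal, sk)
  fk_a <- forward_kinematics(sk, ang)
  fk_b <- forward_kinematics(sk, pf$joint_angles)
  for (j in JOINT_ORDER) {
    expect_equal(quat_angle(fk_a$orient[[j]], fk_b$orient[[j]]) * 180 / pi, 0,
                 tolerance = 1e-6)
  }
  expect_equal(unname(pf$bends), unname(tr$bends[30, ]), tolerance = 1e-6)

  expect_error(states_to_posture(st[-2], cal, sk), "waist")
  bad <- st; bad$chest$t <- 0.5
  expect_error(states_to_posture(bad, cal, sk), "10 ms")
})

test_that("rule classifier reproduces the taxonomy truth table", {
  expect_equal(classify_by_rules(0, 0, 0), 1L)
  expect_equal(classify_by_rules(60, 90, 40), 3L)
  expect_equal(classify_by_rules(30, 80, 120), 5L)
  # priority: supine outranks slightly-bending inside the overlap
  expect_equal(classify_by_rules(30, 60, 30), 7L)
  # half-squat vs squat separated by the knee range boundary at 100
  expect_equal(classify_by_rules(30, 80, 99.9), 4L)
  expect_equal(classify_by_rules(30, 80, 100), 5L)
  # left-closed right-open boundaries
  expect_equal(classify_by_rules(15, 5, 5), 2L)
  expect_true(is.na(classify_by_rules(120, 0, 0)))
  # sitting: upright torso, flexed hip, straight knee
  expect_equal(classify_by_rules(0, 50, 0), 6L)
})

test_that("BVH export round-trips and carries correct header arithmetic", {
  path <- tempfile(fileext = ".bvh")
  # one neutral frame -> all-zero motion line
  export_bvh(sk, neutral_angles(), path)
  bvh <- read_bvh(path)
  expect_equal(bvh$frame_time, 0.01, tolerance = 1e-9)
  expect_equal(nrow(bvh$motion), 1)
  expect_equal(max(abs(bvh$motion)), 0)
  expect_equal(bvh$joints, JOINT_ORDER)

  tr <- generate_posture_trajectory(5, 1, seed = 5)
  export_bvh(sk, tr$angles, path, frame_time = 0.01)
  bvh <- read_bvh(path)
  expect_equal(nrow(bvh$motion), 100)
  back <- bvh$angles[, JOINT_ORDER, ] * 180 / pi
  orig <- tr$angles * 180 / pi
  expect_lt(max(abs(back - orig)), 0.01)
})
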