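sk <- skeleton_from_height(1580)

# aligned tracker-state data.frames from a motion trace (noiseless truth)
trace_states <- function(tr) {
  sim <- imu_from_motion(tr, sk, seed = 1)
  out <- lapply(TRACKER_IDS, function(id) {
    tru <- sim$truth[[id]]
    data.frame(t = tru$t, qw = tru$qw, qx = tru$qx, qy = tru$qy, qz = tru$qz,
               vx = tru$vx, vy = tru$vy, vz = tru$vz,
               dx = tru$px, dy = tru$py, dz = tru$pz)
  })
  names(out) <- TRACKER_IDS
  out
}

test_that("extract_features emits 36 named features, zero for standing still", {
  nm <- feature_names()
  expect_length(nm, 36)
  expect_equal(sum(grepl("_d[xyz]$", nm)), 18)
  expect_equal(sum(grepl("_r[xyz]$", nm)), 18)

  st <- trace_states(constant_trace(c(0, 0, 0, 0, 0), n = 10, label = 1L))
  f <- extract_features(st)
  expect_equal(dim(f), c(10, 36))
  expect_equal(max(abs(f)), 0, tolerance = 1e-9)
})

test_that("single-joint motion shows up in exactly the expected features", {
  # frame 1 neutral, then chest pitched 30 degrees forward
  b <- rbind(c(0, 0, 0, 0, 0), matrix(rep(c(30, 0, 0, 0, 0), each = 9), 9, 5))
  colnames(b) <- c("torso", "hip_l", "hip_r", "knee_l", "knee_r")
  tr <- structure(list(t = (0:9) / 100, angles = imuposture:::bends_to_angles(b),
                       bends = b, labels = rep(1L, 10), rate = 100),
                  class = "motion_trace")
  # the instantaneous pose jump exceeds sensor full scale; the saturation
  # warning is expected and irrelevant here (only the truth poses are used)
  st <- suppressWarnings(trace_states(tr))
  f <- extract_features(st)
  rot <- f[10, grepl("_r[xyz]$", colnames(f))]
  big <- names(rot)[abs(rot) > 1]
  expect_equal(big, "chest_rx")                   # pitch of the chest segment
  expect_equal(unname(abs(f[10, "chest_rx"])), 30, tolerance = 1e-6)
  # chest displacement relative to the segment start is nonzero
  expect_gt(max(abs(f[10, c("chest_dx", "chest_dy", "chest_dz")])), 0.01)
  # untouched trackers show no displacement
  expect_equal(max(abs(f[, c("waist_dx", "l_ankle_dz")])), 0, tolerance = 1e-9)

  misaligned <- st
  misaligned$chest$t <- misaligned$chest$t + 1
  expect_error(extract_features(misaligned), "misaligned")
})

test_that("sliding-window counts follow floor((L - 50)/5) + 1 per segment", {
  f1 <- matrix(0, 50, 36, dimnames = list(NULL, feature_names()))
  ds <- sliding_windows(f1, rep(3L, 50))
  expect_equal(n_windows(ds), 1)
  expect_equal(ds$y, 3L)

  ds0 <- sliding_windows(f1[1:49, ], rep(3L, 49))
  expect_equal(n_windows(ds0), 0)

  # the full-length standing task: 121,800 ms at 100 Hz -> 2,427 windows
  n <- 12180
  f <- matrix(0, n, 36, dimnames = list(NULL, feature_names()))
  ds <- sliding_windows(f, rep(1L, n))
  expect_equal(n_windows(ds), (12180 - 50) %/% 5 + 1)
  expect_equal(n_windows(ds), 2427)
})

test_that("windows are label-pure and never cross excluded frames", {
  n <- 300
  labels <- c(rep(1L, 120), rep(NA_integer_, 40), rep(4L, 140))
  f <- matrix(seq_len(n), n, 36)
  colnames(f) <- feature_names()
  ds <- sliding_windows(f, labels)
  expect_equal(n_windows(ds), ((120 - 50) %/% 5 + 1) + ((140 - 50) %/% 5 + 1))
  # frame indices recorded in the features: no window touches the NA block
  for (i in seq_len(n_windows(ds))) {
    idx <- ds$x[i, , 1]
    expect_equal(idx, seq(idx[1], idx[1] + 49))          # contiguity
    expect_true(all(idx <= 120) || all(idx > 160))       # purity
  }
  # stride-5 reconstruction covers frames [1, 50 + 5(k-1)] of the segment
  first_seg <- which(ds$y == 1L)
  k <- length(first_seg)
  covered <- sort(unique(as.vector(vapply(first_seg, function(i) ds$x[i, , 1],
                                          numeric(50)))))
  expect_equal(covered, seq_len(50 + 5 * (k - 1)))
})

test_that("the 4:1 split reproduces the published train/test arithmetic", {
  ds <- structure(list(x = array(0, c(16004, 1, 1)), y = rep(1L, 16004),
                       feature_names = "f", window = 1, stride = 1),
                  class = "windowed_dataset")
  sp <- split_dataset(ds, ratio = 0.2, seed = 42)
  expect_equal(n_windows(sp$test), 3201)
  expect_equal(n_windows(sp$train), 12803)
  expect_equal(sort(c(sp$test_idx, setdiff(1:16004, sp$test_idx))), 1:16004)

  sp2 <- split_dataset(ds, ratio = 0.2, seed = 42)
  expect_identical(sp$test_idx, sp2$test_idx)   # same seed, same split
  sp3 <- split_dataset(ds, ratio = 0.2, seed = 43)
  expect_false(identical(sp$test_idx, sp3$test_idx))

  small <- subset_windows(ds, 1:4)
  expect_error(split_dataset(small), "at least 5")
})

test_that("grouped split keeps whole label runs together", {
  y <- rep(c(1L, 2L, 3L, 4L, 5L), each = 20)
  ds <- structure(list(x = array(0, c(100, 1, 1)), y = y,
                       feature_names = "f", window = 1, stride = 1),
                  class = "windowed_dataset")
  sp <- split_dataset(ds, ratio = 0.2, seed = 1, grouped = TRUE)
  runs <- split(seq_along(y), rep(1:5, each = 20))
  for (r in runs) {
    expect_true(all(r %in% sp$test_idx) || !any(r %in% sp$test_idx))
  }
})
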