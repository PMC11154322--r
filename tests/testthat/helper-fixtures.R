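# Shared fixtures: random rotations, closed-form rotation matrices, and
# constructors for small synthetic inputs. All randomness is locally seeded.

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# Independent rotation-matrix oracles (never built through the quat_* path)
rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a),
                              0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

# Rodrigues formula: matrix exponential of the skew matrix of v
rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th == 0) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Constant-posture motion trace (no tremor/drift) from fixed bend angles.
constant_trace <- function(bends, n = 100, rate = 100, label = NA_integer_) {
  b <- matrix(rep(bends, each = n), n, 5,
              dimnames = list(NULL, c("torso", "hip_l", "hip_r", "knee_l", "knee_r")))
  structure(list(t = (seq_len(n) - 1) / rate,
                 angles = imuposture:::bends_to_angles(b),
                 bends = b,
                 labels = rep(label, n), rate = rate),
            class = "motion_trace")
}

# Tracker-state lists at a single instant from a joint-angle matrix.
states_from_angles <- function(sk, angles, t = 0) {
  fk <- forward_kinematics(sk, angles)
  st <- lapply(TRACKER_IDS, function(id) list(q = fk$orient[[TRACKER_SEGMENT[[id]]]], t = t))
  names(st) <- TRACKER_IDS
  st
}

# Tiny separable toy dataset for classifier tests: class k has a sinusoid of
# frequency k on feature 1.
toy_windows <- function(n_per_class = 40, classes = 2, T = 20, F = 3, seed = 1) {
  set.seed(seed)
  N <- n_per_class * classes
  x <- array(stats::rnorm(N * T * F, sd = 0.1), c(N, T, F))
  y <- rep(seq_len(classes), each = n_per_class)
  tt <- seq(0, 1, length.out = T)
  for (i in seq_len(N)) x[i, , 1] <- x[i, , 1] + sin(2 * pi * y[i] * tt)
  structure(list(x = x, y = y, feature_names = paste0("f", seq_len(F)),
                 window = T, stride = 1),
            class = "windowed_dataset")
}
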