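# Hierarchical digital-human model of the torso and lower limbs: joint tree,
# anthropometric segment lengths, two-pose tracker calibration, forward
# kinematics, posture-angle extraction, the rule-based posture taxonomy,
# and BVH export.

#' Joint order of the digital human model
#'
#' Torso and lower-limb joints, parents preceding children: pelvis (root),
#' lumbar, thoracic, and per side hip, knee, ankle. Thoracic, lumbar and hip
#' joints have 3 rotational degrees of freedom (yaw/pitch/roll), the knee 1
#' (pitch), the ankle 2 (pitch/roll).
#' @export
JOINT_ORDER <- c("pelvis", "lumbar", "thoracic",
                 "l_hip", "l_knee", "l_ankle",
                 "r_hip", "r_knee", "r_ankle")

JOINT_PARENT <- c(pelvis = NA, lumbar = "pelvis", thoracic = "lumbar",
                  l_hip = "pelvis", l_knee = "l_hip", l_ankle = "l_knee",
                  r_hip = "pelvis", r_knee = "r_hip", r_ankle = "r_knee")

JOINT_DOF <- list(
  pelvis = c("yaw", "pitch", "roll"),
  lumbar = c("yaw", "pitch", "roll"),
  thoracic = c("yaw", "pitch", "roll"),
  l_hip = c("yaw", "pitch", "roll"),
  l_knee = "pitch",
  l_ankle = c("pitch", "roll"),
  r_hip = c("yaw", "pitch", "roll"),
  r_knee = "pitch",
  r_ankle = c("pitch", "roll")
)

#' Tracker-to-segment assignment
#'
#' Each tracker rides the bone emanating from the named joint: the chest
#' tracker the chest segment above the thoracic joint, the waist tracker the
#' pelvis, knee trackers the femur (knee end), ankle trackers the tibia
#' (ankle end).
#' @export
TRACKER_SEGMENT <- c(chest = "thoracic", waist = "pelvis",
                     l_knee = "l_hip", l_ankle = "l_knee",
                     r_knee = "r_hip", r_ankle = "r_knee")

# Drillis-Contini style segment ratios (fraction of stature).
DEFAULT_PROPORTIONS <- list(
  pelvis_to_lumbar = 0.05,
  pelvis_to_chest = 0.288,   # pelvis root to thoracic joint
  chest_up = 0.100,          # chest segment above the thoracic joint
  hip_half_width = 0.0955,
  femur = 0.245,
  tibia = 0.246,
  foot = 0.039
)

#' Build a skeleton from subject stature
#'
#' Segment lengths are stature times standard anthropometric ratios
#' (Drillis-Contini table), all overridable through `proportions`.
#' World/rest frame: Y down, Z forward, X right; the rest pose is upright.
#'
#' @param height_mm Subject stature in mm, in `[1000, 2500]`.
#' @param proportions Named list of stature fractions; see
#'   `imuposture:::DEFAULT_PROPORTIONS` for the keys.
#' @return Object of class `skeleton`: joint table (`joints`), per-joint
#'   rest offsets in mm (`offsets`), degrees of freedom (`dof`), segment
#'   lengths (`segment_lengths`), `subject_height`.
#' @export
skeleton_from_height <- function(height_mm = 1580, proportions = list()) {
  if (!is.numeric(height_mm) || height_mm < 1000 || height_mm > 2500) {
    stop("height_mm must be in [1000, 2500]")
  }
  p <- utils::modifyList(DEFAULT_PROPORTIONS, proportions)
  H <- height_mm
  offsets <- rbind(
    pelvis = c(0, 0, 0),
    lumbar = c(0, -p$pelvis_to_lumbar * H, 0),
    thoracic = c(0, -(p$pelvis_to_chest - p$pelvis_to_lumbar) * H, 0),
    l_hip = c(-p$hip_half_width * H, 0, 0),
    l_knee = c(0, p$femur * H, 0),
    l_ankle = c(0, p$tibia * H, 0),
    r_hip = c(p$hip_half_width * H, 0, 0),
    r_knee = c(0, p$femur * H, 0),
    r_ankle = c(0, p$tibia * H, 0)
  )[JOINT_ORDER, ]
  end_sites <- list(
    thoracic = c(0, -p$chest_up * H, 0),
    l_ankle = c(0, p$foot * H, 0),
    r_ankle = c(0, p$foot * H, 0)
  )
  seg <- c(pelvis_to_lumbar = p$pelvis_to_lumbar * H,
           lumbar_to_chest = (p$pelvis_to_chest - p$pelvis_to_lumbar) * H,
           chest_up = p$chest_up * H,
           hip_half_width = p$hip_half_width * H,
           femur = p$femur * H,
           tibia = p$tibia * H,
           foot = p$foot * H)
  stopifnot(all(seg > 0))
  structure(list(joints = JOINT_ORDER, parent = JOINT_PARENT, dof = JOINT_DOF,
                 offsets = offsets, end_sites = end_sites,
                 segment_lengths = seg, subject_height = H,
                 proportions = p),
            class = "skeleton")
}

#' Neutral (all-zero) joint-angle matrix
#'
#' Joint angles are a 9 x 3 matrix, rows in [JOINT_ORDER], columns
#' `yaw, pitch, roll` in radians (intrinsic Y-X-Z decomposition).
#' @export
neutral_angles <- function() {
  a <- matrix(0, length(JOINT_ORDER), 3,
              dimnames = list(JOINT_ORDER, c("yaw", "pitch", "roll")))
  a
}

check_dof <- function(angles, tol = 1e-9) {
  for (j in JOINT_ORDER) {
    off <- setdiff(c("yaw", "pitch", "roll"), JOINT_DOF[[j]])
    if (length(off) && any(abs(angles[j, off]) > tol)) {
      stop(sprintf("joint '%s' has a nonzero angle outside its degrees of freedom (%s)",
                   j, paste(off, collapse = ",")))
    }
  }
  invisible(TRUE)
}

#' Forward kinematics
#'
#' Composes per-joint rotations down the tree: child world orientation =
#' parent orientation times the child's local Y-X-Z rotation; child position
#' = parent position + parent orientation applied to the rest-bone offset.
#' Root (pelvis) sits at the origin.
#'
#' @param sk A [skeleton_from_height()].
#' @param angles 9 x 3 joint-angle matrix in radians (see [neutral_angles()]);
#'   angles outside a joint's degrees of freedom must be zero.
#' @return List with `pos` (9 x 3 world positions, mm), `orient` (named list
#'   of world quaternions) and `end_sites` (world positions of the terminal
#'   bone tips, mm).
#' @export
forward_kinematics <- function(sk, angles) {
  if (any(!is.finite(angles))) stop("non-finite joint angles")
  check_dof(angles)
  pos <- matrix(0, length(JOINT_ORDER), 3,
                dimnames = list(JOINT_ORDER, c("x", "y", "z")))
  orient <- vector("list", length(JOINT_ORDER))
  names(orient) <- JOINT_ORDER
  for (j in JOINT_ORDER) {
    ql <- ypr_to_quat(angles[j, "yaw"], angles[j, "pitch"], angles[j, "roll"])
    par <- sk$parent[[j]]
    if (is.na(par)) {
      pos[j, ] <- c(0, 0, 0)
      orient[[j]] <- ql
    } else {
      pos[j, ] <- pos[par, ] + quat_rotate(orient[[par]], sk$offsets[j, ])
      orient[[j]] <- quat_mul(orient[[par]], ql)
    }
  }
  ends <- lapply(names(sk$end_sites), function(j) {
    pos[j, ] + quat_rotate(orient[[j]], sk$end_sites[[j]])
  })
  names(ends) <- names(sk$end_sites)
  list(pos = pos, orient = orient, end_sites = ends)
}

# ---- Bend angles and the posture taxonomy ---------------------------------

# Sagittal-plane angle of a segment's down-axis from the world down axis,
# positive toward forward (+Z).
sagittal_angle_down <- function(q) {
  v <- quat_rotate(q, c(0, 1, 0))
  atan2(v[3], v[2]) * 180 / pi
}

#' Derived bend angles from segment orientations
#'
#' * `torso`: angle of the pelvis-to-chest axis from world up, projected to
#'   the sagittal plane, flexion (forward lean) positive;
#' * `hip_l/r`: sagittal angle between the trunk axis (continued downward)
#'   and the femur axis;
#' * `knee_l/r`: sagittal angle between the femur extension and the tibia.
#' Standing is approximately 0 everywhere; a deep squat exceeds 100 degrees
#' at the knee.
#'
#' @param seg Named list of segment world quaternions with elements
#'   `pelvis`, `thoracic` (chest segment), `l_hip`/`r_hip` (femurs),
#'   `l_knee`/`r_knee` (tibias).
#' @return Named numeric bends in degrees, wrapped to `[-180, 180]`.
#' @export
bend_angles <- function(seg) {
  seg <- lapply(seg, function(q) unname(as.numeric(q)))
  u <- quat_rotate(seg$thoracic, c(0, -1, 0))
  torso <- atan2(u[3], -u[2]) * 180 / pi
  th_p <- sagittal_angle_down(seg$pelvis)
  th_fl <- sagittal_angle_down(seg$l_hip)
  th_fr <- sagittal_angle_down(seg$r_hip)
  th_tl <- sagittal_angle_down(seg$l_knee)
  th_tr <- sagittal_angle_down(seg$r_knee)
  wrap <- function(a) ((a + 180) %% 360) - 180
  c(torso = wrap(torso),
    hip_l = wrap(th_fl - th_p), hip_r = wrap(th_fr - th_p),
    knee_l = wrap(th_fl - th_tl), knee_r = wrap(th_fr - th_tr))
}

#' Posture taxonomy angle ranges
#'
#' Torso / hip / knee bending-angle ranges (degrees) defining the seven
#' basic operation postures: 1 standing, 2 slightly bending, 3 deep bending,
#' 4 half-squatting, 5 squatting, 6 sitting, 7 supine.
#' @export
POSTURE_RANGES <- local({
  m <- rbind(
    c(-15, 15, -17, 5, -3, 5),     # 1 standing
    c(15, 40, 5, 50, 5, 60),       # 2 slightly bending
    c(40, 84, 70, 116, 5, 70),     # 3 deep bending
    c(15, 40, 50, 116, 60, 100),   # 4 half squatting
    c(15, 40, 50, 116, 100, 150),  # 5 squatting
    c(-15, 15, 30, 70, -3, 5),     # 6 sitting
    c(-5, 40, 50, 100, 5, 60)      # 7 supine
  )
  dimnames(m) <- list(as.character(1:7),
                      c("torso_lo", "torso_hi", "hip_lo", "hip_hi",
                        "knee_lo", "knee_hi"))
  m
})

#' Names of the seven posture classes
#' @export
POSTURE_NAMES <- c("standing", "slightly bending", "deep bending",
                   "half squatting", "squatting", "sitting", "supine")

# Overlapping ranges are disambiguated by a most-specific-first priority.
RULE_PRIORITY <- c(7L, 5L, 4L, 3L, 6L, 2L, 1L)

#' Rule-based posture classification
#'
#' Returns the first label (priority order 7, 5, 4, 3, 6, 2, 1) whose three
#' angle ranges all contain the frame's torso, hip and knee bends; ranges are
#' closed on the left, open on the right. Asymmetric frames use the max of
#' the two sides for hip and knee. `NA` means unclassified.
#'
#' @param torso,hip,knee Bend angles in degrees (vectors recycle).
#' @return Integer vector of labels 1-7 or `NA`.
#' @export
classify_by_rules <- function(torso, hip, knee) {
  n <- max(length(torso), length(hip), length(knee))
  torso <- rep_len(torso, n); hip <- rep_len(hip, n); knee <- rep_len(knee, n)
  out <- rep(NA_integer_, n)
  for (lab in rev(RULE_PRIORITY)) {
    r <- POSTURE_RANGES[lab, ]
    hit <- torso >= r["torso_lo"] & torso < r["torso_hi"] &
      hip >= r["hip_lo"] & hip < r["hip_hi"] &
      knee >= r["knee_lo"] & knee < r["knee_hi"]
    out[hit] <- lab   # later (higher-priority) labels overwrite
  }
  out
}

#' Classify a posture frame
#'
#' Convenience wrapper over [classify_by_rules()] taking the named bend
#' vector of [bend_angles()].
#'
#' @param bends Named numeric with `torso`, `hip_l`, `hip_r`, `knee_l`,
#'   `knee_r` (degrees).
#' @export
classify_frame <- function(bends) {
  classify_by_rules(bends[["torso"]],
                    max(bends[["hip_l"]], bends[["hip_r"]]),
                    max(bends[["knee_l"]], bends[["knee_r"]]))
}

# ---- Calibration -----------------------------------------------------------

#' Two-pose tracker calibration
#'
#' From the upright pose every segment is at its rest (identity) world
#' orientation, so the per-tracker mounting quaternion is the conjugate of
#' the upright tracker orientation (`segment = tracker x mounting`). The
#' skiing pose (hips and knees flexed, torso pitched forward) resolves the
#' sign/axis ambiguity: after applying the recovered mounting, both femur
#' segments must show a forward pitch above 20 degrees, otherwise the
#' offending tracker is reported as mis-mounted.
#'
#' @param upright,ski Named lists of world-orientation quaternions per
#'   tracker (all of [TRACKER_IDS]).
#' @param min_thigh_pitch_deg Ski-pose disambiguation threshold.
#' @return Object of class `calibration` with `mounting_q` (named list) and
#'   `captured_at`.
#' @export
calibrate <- function(upright, ski, min_thigh_pitch_deg = 20) {
  missing <- setdiff(TRACKER_IDS, names(upright))
  if (length(missing)) stop("upright pose misses trackers: ",
                            paste(missing, collapse = ", "))
  missing <- setdiff(TRACKER_IDS, names(ski))
  if (length(missing)) stop("ski pose misses trackers: ",
                            paste(missing, collapse = ", "))
  mounting <- lapply(upright[TRACKER_IDS], function(q) quat_canonical(quat_conj(q)))
  names(mounting) <- TRACKER_IDS
  for (tr in c("l_knee", "r_knee")) {  # femur-fixed trackers
    seg_ski <- quat_mul(ski[[tr]], mounting[[tr]])
    pitch <- sagittal_angle_down(seg_ski)
    if (!(pitch > min_thigh_pitch_deg)) {
      stop(sprintf("mis-mounted tracker '%s': ski-pose thigh pitch %.1f deg is not > %.0f deg",
                   tr, pitch, min_thigh_pitch_deg))
    }
  }
  structure(list(mounting_q = mounting, captured_at = 0),
            class = "calibration")
}

#' Identity calibration (trackers mounted exactly on-axis)
#' @export
identity_calibration <- function() {
  structure(list(mounting_q = stats::setNames(
    rep(list(quat_identity()), length(TRACKER_IDS)), TRACKER_IDS),
    captured_at = 0), class = "calibration")
}

# ---- Tracker states -> posture --------------------------------------------

#' Posture frame from per-tracker states
#'
#' Applies the mounting calibration to obtain segment orientations, then
#' decomposes relative parent-to-child rotations into joint angles
#' (intrinsic yaw-pitch-roll, restricted to each joint's degrees of
#' freedom; the torso rotation is split equally between the lumbar and
#' thoracic joints) and computes the derived bend angles.
#'
#' @param states Named list over [TRACKER_IDS] of [tracker_state()] objects
#'   (or bare quaternions). Timestamps must agree within 10 ms.
#' @param cal A [calibrate()] result.
#' @param sk A [skeleton_from_height()].
#' @return Object of class `posture_frame`: `t`, `joint_angles` (9 x 3, rad),
#'   `bends` (degrees), `label` (rule classification).
#' @export
states_to_posture <- function(states, cal = identity_calibration(),
                              sk = skeleton_from_height()) {
  missing <- setdiff(TRACKER_IDS, names(states))
  if (length(missing)) {
    stop("missing trackers: ", paste(missing, collapse = ", "))
  }
  getq <- function(s) if (is.list(s)) s$q else s
  gett <- function(s) if (is.list(s)) s$t else NA_real_
  tt <- vapply(states[TRACKER_IDS], gett, numeric(1))
  t0 <- if (all(is.na(tt))) 0 else stats::median(tt, na.rm = TRUE)
  if (any(abs(tt - t0) > 0.010, na.rm = TRUE)) {
    stop("tracker timestamps differ by more than 10 ms; align streams first")
  }
  seg <- lapply(TRACKER_IDS, function(tr) {
    quat_mul(getq(states[[tr]]), cal$mounting_q[[tr]])
  })
  names(seg) <- TRACKER_SEGMENT[TRACKER_IDS]

  angles <- neutral_angles()
  angles["pelvis", ] <- quat_to_ypr(seg$pelvis)
  torso_rel <- quat_mul(quat_conj(seg$pelvis), seg$thoracic)
  half <- quat_from_rotvec(quat_to_rotvec(torso_rel) / 2)
  angles["lumbar", ] <- quat_to_ypr(half)
  angles["thoracic", ] <- quat_to_ypr(half)
  for (side in c("l", "r")) {
    fem <- seg[[paste0(side, "_hip")]]
    tib <- seg[[paste0(side, "_knee")]]
    angles[paste0(side, "_hip"), ] <- quat_to_ypr(quat_mul(quat_conj(seg$pelvis), fem))
    knee_ypr <- quat_to_ypr(quat_mul(quat_conj(fem), tib))
    angles[paste0(side, "_knee"), "pitch"] <- knee_ypr["pitch"]  # 1-dof joint
  }
  bends <- bend_angles(seg)
  structure(list(t = t0, joint_angles = angles, bends = bends,
                 label = classify_frame(bends)),
            class = "posture_frame")
}

#' Posture frames for aligned tracker-state sequences
#'
#' Vectorized driver of [states_to_posture()] over whole sessions.
#'
#' @param state_dfs Named list over [TRACKER_IDS] of data.frames from
#'   [states_to_df()], with identical timestamp grids.
#' @param cal A [calibrate()] result.
#' @param sk A [skeleton_from_height()].
#' @return List with `t`, `angles` (n x 9 x 3 array, rad), `bends`
#'   (n x 5 matrix, degrees), `labels` (rule classification per frame).
#' @export
posture_from_states <- function(state_dfs, cal = identity_calibration(),
                                sk = skeleton_from_height()) {
  missing <- setdiff(TRACKER_IDS, names(state_dfs))
  if (length(missing)) stop("missing trackers: ", paste(missing, collapse = ", "))
  n <- nrow(state_dfs[[TRACKER_IDS[1]]])
  for (tr in TRACKER_IDS) stopifnot(nrow(state_dfs[[tr]]) == n)
  tt <- state_dfs[[TRACKER_IDS[1]]]$t
  qs <- lapply(state_dfs[TRACKER_IDS], function(df) {
    as.matrix(df[, c("qw", "qx", "qy", "qz")])
  })
  angles <- array(0, c(n, length(JOINT_ORDER), 3),
                  dimnames = list(NULL, JOINT_ORDER, c("yaw", "pitch", "roll")))
  bends <- matrix(0, n, 5,
                  dimnames = list(NULL, c("torso", "hip_l", "hip_r", "knee_l", "knee_r")))
  for (i in seq_len(n)) {
    st <- lapply(TRACKER_IDS, function(tr) list(q = qs[[tr]][i, ], t = tt[i]))
    names(st) <- TRACKER_IDS
    pf <- states_to_posture(st, cal, sk)
    angles[i, , ] <- pf$joint_angles
    bends[i, ] <- pf$bends
  }
  labels <- classify_by_rules(bends[, "torso"],
                              pmax(bends[, "hip_l"], bends[, "hip_r"]),
                              pmax(bends[, "knee_l"], bends[, "knee_r"]))
  list(t = tt, angles = angles, bends = bends, labels = labels)
}

# ---- BVH export ------------------------------------------------------------

bvh_children <- function(j) JOINT_ORDER[!is.na(JOINT_PARENT) & JOINT_PARENT == j]

write_bvh_joint <- function(con, sk, j, indent) {
  pad <- strrep("\t", indent)
  off <- sk$offsets[j, ] / 10  # mm -> cm
  kids <- bvh_children(j)
  if (j == "pelvis") {
    writeLines(sprintf("ROOT %s", j), con)
  } else {
    writeLines(sprintf("%sJOINT %s", pad, j), con)
  }
  writeLines(sprintf("%s{", pad), con)
  writeLines(sprintf("%s\tOFFSET %.6f %.6f %.6f", pad, off[1], off[2], off[3]), con)
  if (j == "pelvis") {
    writeLines(sprintf("%s\tCHANNELS 6 Xposition Yposition Zposition Yrotation Xrotation Zrotation", pad), con)
  } else {
    writeLines(sprintf("%s\tCHANNELS 3 Yrotation Xrotation Zrotation", pad), con)
  }
  for (k in kids) write_bvh_joint(con, sk, k, indent + 1)
  if (!is.null(sk$end_sites[[j]])) {
    es <- sk$end_sites[[j]] / 10
    writeLines(sprintf("%s\tEnd Site", pad), con)
    writeLines(sprintf("%s\t{", pad), con)
    writeLines(sprintf("%s\t\tOFFSET %.6f %.6f %.6f", pad, es[1], es[2], es[3]), con)
    writeLines(sprintf("%s\t}", pad), con)
  }
  writeLines(sprintf("%s}", pad), con)
}

#' Export a motion to BVH
#'
#' Standard hierarchical motion-capture text format. The HIERARCHY section
#' mirrors the joint tree with OFFSETs in cm; rotation channels are
#' `Yrotation Xrotation Zrotation` (intrinsic yaw-pitch-roll, degrees),
#' matching the package's joint-angle decomposition; axes are the package's
#' Y-down world frame.
#'
#' @param sk A [skeleton_from_height()].
#' @param angles n x 9 x 3 array of joint angles in radians (frames x
#'   [JOINT_ORDER] x yaw/pitch/roll), or a single 9 x 3 matrix.
#' @param path Output file.
#' @param frame_time Seconds per frame (default 0.01 = 100 Hz).
#' @param root_pos Optional n x 3 root displacement (mm; written in cm).
#' @export
export_bvh <- function(sk, angles, path, frame_time = 0.01, root_pos = NULL) {
  if (length(dim(angles)) == 2) {
    angles <- array(angles, c(1, dim(angles)),
                    dimnames = c(list(NULL), dimnames(angles)))
  }
  n <- dim(angles)[1]
  if (n < 1) stop("need at least one frame")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("HIERARCHY", con)
  write_bvh_joint(con, sk, "pelvis", 0)
  writeLines("MOTION", con)
  writeLines(sprintf("Frames: %d", n), con)
  writeLines(sprintf("Frame Time: %.7f", frame_time), con)
  deg <- angles * 180 / pi
  for (i in seq_len(n)) {
    rp <- if (is.null(root_pos)) c(0, 0, 0) else root_pos[i, ] / 10
    vals <- c(rp, as.vector(t(deg[i, JOINT_ORDER, c("yaw", "pitch", "roll")])))
    writeLines(paste(sprintf("%.6f", vals), collapse = " "), con)
  }
  invisible(path)
}

#' Parse a BVH file
#'
#' Minimal reader for files produced by [export_bvh()] (and other BVH files
#' using 3-channel rotation joints plus a 6-channel root).
#'
#' @param path BVH file.
#' @return List: `joints` (in file order), `offsets_cm`, `channels`,
#'   `frame_time`, `motion` (frames x channels matrix), and `angles`
#'   (n x joints x yaw/pitch/roll array, radians).
#' @export
read_bvh <- function(path) {
  lines <- trimws(readLines(path))
  joints <- character(); offsets <- list(); channels <- list()
  cur <- NULL; in_end <- FALSE
  i <- 1
  while (i <= length(lines) && lines[i] != "MOTION") {
    ln <- lines[i]
    if (grepl("^(ROOT|JOINT) ", ln)) {
      cur <- sub("^(ROOT|JOINT) ", "", ln)
      joints <- c(joints, cur)
    } else if (grepl("^End Site", ln)) {
      in_end <- TRUE
    } else if (grepl("^OFFSET ", ln)) {
      v <- as.numeric(strsplit(sub("^OFFSET ", "", ln), "\\s+")[[1]])
      if (!in_end) offsets[[cur]] <- v
    } else if (grepl("^CHANNELS ", ln)) {
      ch <- strsplit(ln, "\\s+")[[1]][-(1:2)]
      channels[[cur]] <- ch
    } else if (ln == "}") {
      if (in_end) in_end <- FALSE
    }
    i <- i + 1
  }
  stopifnot(lines[i] == "MOTION")
  nframes <- as.integer(sub("Frames:\\s*", "", lines[i + 1]))
  ft <- as.numeric(sub("Frame Time:\\s*", "", lines[i + 2]))
  motion <- do.call(rbind, lapply(lines[(i + 3):(i + 2 + nframes)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]])
  }))
  angles <- array(0, c(nframes, length(joints), 3),
                  dimnames = list(NULL, joints, c("yaw", "pitch", "roll")))
  col <- 1
  for (j in joints) {
    for (ch in channels[[j]]) {
      tgt <- switch(ch, Yrotation = "yaw", Xrotation = "pitch",
                    Zrotation = "roll", NA)
      if (!is.na(tgt)) angles[, j, tgt] <- motion[, col] * pi / 180
      col <- col + 1
    }
  }
  list(joints = joints, offsets_cm = offsets, channels = channels,
       frame_time = ft, motion = motion, angles = angles)
}
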