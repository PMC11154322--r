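# Feature extraction, sliding-window segmentation and train/test split.
#
# Per frame, each of the six tracked joints contributes its cumulative world
# displacement (m, zeroed at the start of the containing labeled segment)
# and the rotation angles of its calibrated segment orientation about the
# three axes (yaw-pitch-roll, degrees): 6 joints x 6 = 36 features.

#' Feature names of the 36-dimensional frame vector
#' @export
feature_names <- function() {
  as.vector(vapply(TRACKER_IDS, function(tr) {
    paste(tr, c("dx", "dy", "dz", "rx", "ry", "rz"), sep = "_")
  }, character(6)))
}

#' Extract per-frame features from tracker-state sequences
#'
#' @param state_dfs Named list over [TRACKER_IDS] of aligned data.frames
#'   from [states_to_df()] (identical timestamp grids).
#' @param cal A [calibrate()] result applied before the rotation
#'   decomposition.
#' @param labels Optional per-frame labels (`NA` = excluded); cumulative
#'   displacement is re-zeroed at the start of every contiguous labeled
#'   segment. Without labels it is zeroed at the stream start.
#' @return n x 36 numeric matrix with [feature_names()] as columns.
#'   Rotation features `rx, ry, rz` are the pitch, yaw and roll of the
#'   segment orientation in degrees.
#' @export
extract_features <- function(state_dfs, cal = identity_calibration(),
                             labels = NULL) {
  missing <- setdiff(TRACKER_IDS, names(state_dfs))
  if (length(missing)) stop("missing trackers: ", paste(missing, collapse = ", "))
  n <- nrow(state_dfs[[TRACKER_IDS[1]]])
  tt <- state_dfs[[TRACKER_IDS[1]]]$t
  for (tr in TRACKER_IDS) {
    df <- state_dfs[[tr]]
    if (nrow(df) != n || max(abs(df$t - tt)) > 1e-9) {
      stop("misaligned tracker-state inputs (tracker ", tr, ")")
    }
  }
  if (!is.null(labels) && length(labels) != n) stop("labels length mismatch")

  # segment ids: contiguous runs of an identical (non-NA) label
  if (is.null(labels)) {
    seg_id <- rep(1L, n)
  } else {
    r <- rle(ifelse(is.na(labels), -1L, as.integer(labels)))
    seg_id <- rep(seq_along(r$lengths), r$lengths)
  }
  seg_start <- !duplicated(seg_id)

  out <- matrix(0, n, 36, dimnames = list(NULL, feature_names()))
  col0 <- 0
  for (tr in TRACKER_IDS) {
    df <- state_dfs[[tr]]
    d <- as.matrix(df[, c("dx", "dy", "dz")])
    base <- d[seg_start, , drop = FALSE][seg_id, , drop = FALSE]
    out[, col0 + 1:3] <- d - base
    m <- cal$mounting_q[[tr]]
    for (i in seq_len(n)) {
      q <- quat_mul(c(df$qw[i], df$qx[i], df$qy[i], df$qz[i]), m)
      ypr <- quat_to_ypr(q)
      out[i, col0 + 4:6] <- c(ypr["pitch"], ypr["yaw"], ypr["roll"]) * 180 / pi
    }
    col0 <- col0 + 6
  }
  attr(out, "t") <- tt
  out
}

#' Sliding-window dataset
#'
#' Windows of `window` frames advancing by `stride` are generated
#' independently within each contiguous single-label segment — windows never
#' cross excluded frames or label boundaries, so every window is label-pure.
#' A segment of length L yields `floor((L - window)/stride) + 1` windows
#' (0 when L < window).
#'
#' @param features n x 36 matrix from [extract_features()].
#' @param labels Per-frame integer labels, `NA` = excluded.
#' @param window Window length in frames (default 50 = 0.5 s at 100 Hz).
#' @param stride Window step in frames (default 5).
#' @return Object of class `windowed_dataset`: `x` (N x window x 36 array),
#'   `y` (N labels), `feature_names`, `window`, `stride`.
#' @export
sliding_windows <- function(features, labels, window = 50, stride = 5) {
  stopifnot(nrow(features) == length(labels), window > 0, stride > 0)
  r <- rle(ifelse(is.na(labels), -1L, as.integer(labels)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  xs <- list(); ys <- integer(0)
  for (k in seq_along(r$values)) {
    lab <- r$values[k]
    if (lab < 0) next
    len <- r$lengths[k]
    if (len < window) next
    nw <- (len - window) %/% stride + 1
    for (w in seq_len(nw)) {
      s <- starts[k] + (w - 1) * stride
      xs[[length(xs) + 1]] <- features[s:(s + window - 1), , drop = FALSE]
      ys <- c(ys, lab)
    }
  }
  N <- length(xs)
  x <- array(0, c(N, window, ncol(features)))
  for (i in seq_len(N)) x[i, , ] <- xs[[i]]
  structure(list(x = x, y = ys, feature_names = colnames(features),
                 window = window, stride = stride),
            class = "windowed_dataset")
}

#' Subset a windowed dataset
#' @param ds A `windowed_dataset`.
#' @param i Window indices.
#' @export
subset_windows <- function(ds, i) {
  structure(list(x = ds$x[i, , , drop = FALSE], y = ds$y[i],
                 feature_names = ds$feature_names,
                 window = ds$window, stride = ds$stride),
            class = "windowed_dataset")
}

#' Number of windows
#' @param ds A `windowed_dataset`.
#' @export
n_windows <- function(ds) length(ds$y)

#' Random train/test split of a windowed dataset
#'
#' Uniform window-level split; `|test| = round(N * ratio)`. Adjacent windows
#' share `window - stride` frames, so a window-level split leaks temporal
#' context between train and test; `grouped = TRUE` instead splits whole
#' label segments (contiguous window runs of one label) for a stricter
#' evaluation.
#'
#' @param ds A `windowed_dataset` with at least 5 windows.
#' @param ratio Test fraction (default 0.2, the 4:1 split).
#' @param seed RNG seed (default 42).
#' @param grouped Split contiguous label runs instead of single windows.
#' @return List `train`, `test` (both `windowed_dataset`), `test_idx`.
#' @export
split_dataset <- function(ds, ratio = 0.2, seed = 42, grouped = FALSE) {
  N <- n_windows(ds)
  if (N < 5) stop("need at least 5 windows to split")
  test_idx <- with_seed(seed, {
    if (!grouped) {
      sort(sample.int(N, round(N * ratio)))
    } else {
      runs <- rle(ds$y)
      rid <- rep(seq_along(runs$lengths), runs$lengths)
      pick <- sample(seq_along(runs$lengths),
                     max(1, round(length(runs$lengths) * ratio)))
      which(rid %in% pick)
    }
  })
  train_idx <- setdiff(seq_len(N), test_idx)
  list(train = subset_windows(ds, train_idx),
       test = subset_windows(ds, test_idx),
       test_idx = test_idx)
}
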