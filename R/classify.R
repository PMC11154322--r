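# Posture recognizer: BiLSTM (and unidirectional LSTM baseline) over
# 50-frame windows of the 36 joint features, with the training protocol
# (Adam, lr 0.001, 10 epochs, batch 32, dropout 0.5, L2) and the repeated
# train/test evaluation producing per-class precision/recall/F and a
# confusion matrix.

#' Model configuration
#'
#' Defaults are the recognizer's operating point: 64 hidden units per
#' directional layer, dropout 0.5 on the merged representation, Adam with
#' learning rate 0.001, 10 epochs, batch size 32, categorical cross-entropy,
#' 7 classes. `bidirectional = FALSE` yields the unidirectional LSTM
#' baseline. The L2 coefficient is not part of the published protocol
#' beyond "L2 regularization"; 1e-4 is a conventional default.
#'
#' @param hidden_units Hidden neurons per LSTM direction.
#' @param dropout Dropout fraction on the merged final states.
#' @param learning_rate Adam initial learning rate.
#' @param epochs,batch_size Training schedule.
#' @param l2 L2 penalty coefficient on weight matrices.
#' @param classes Number of posture classes.
#' @param bidirectional Use forward + backward layers.
#' @param val_fraction Fraction of the training set carved out (seeded) as
#'   the validation set for the loss curve.
#' @export
model_config <- function(hidden_units = 64, dropout = 0.5,
                         learning_rate = 0.001, epochs = 10, batch_size = 32,
                         l2 = 1e-4, classes = 7, bidirectional = TRUE,
                         val_fraction = 0.1) {
  stopifnot(hidden_units > 0, epochs > 0, batch_size > 0, classes > 0,
            dropout >= 0, dropout < 1, learning_rate > 0, l2 >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(hidden_units = hidden_units, dropout = dropout,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, l2 = l2, classes = classes,
                 bidirectional = bidirectional, val_fraction = val_fraction),
            class = "model_config")
}

#' Build an untrained posture-recognition model
#'
#' Architecture: window x 36 input, forward (and backward) LSTM with
#' `hidden_units` neurons, concatenation of the final hidden states,
#' dropout, dense layer, softmax over the classes.
#'
#' @param cfg A [model_config()].
#' @param input_dim Features per frame (36).
#' @param seed Weight-initialization seed.
#' @return Object of class `posture_model`.
#' @export
build_model <- function(cfg = model_config(), input_dim = 36, seed = 42) {
  params <- lstm_init_cpp(as.integer(input_dim), as.integer(cfg$hidden_units),
                          as.integer(cfg$classes), isTRUE(cfg$bidirectional),
                          as.integer(seed))
  structure(list(cfg = cfg, params = params, input_dim = input_dim,
                 label_map = seq_len(cfg$classes),
                 feature_names = feature_names()[seq_len(min(36, input_dim))],
                 history = NULL),
            class = "posture_model")
}

#' Number of trainable parameters
#' @param model A `posture_model`.
#' @export
n_params <- function(model) {
  p <- model$params
  n <- length(p$Wd) + length(p$bd)
  for (d in p$dirs) n <- n + length(d$W) + length(d$U) + length(d$b)
  n
}

# windowed x (N x T x F) -> arma cube layout (F x T x N)
windows_to_cube <- function(x) aperm(x, c(3, 2, 1))

labels_to_internal <- function(model, y) {
  iy <- match(y, model$label_map) - 1L
  if (any(is.na(iy))) stop("labels outside the model's label map")
  iy
}

#' Train a posture model
#'
#' Runs the training schedule of the model's [model_config()] on a
#' [sliding_windows()] dataset, carving `val_fraction` of the windows out
#' (seeded) as a validation set for the per-epoch loss curve. Deterministic
#' given `seed`.
#'
#' @param model A [build_model()] result.
#' @param ds `windowed_dataset` (training portion).
#' @param seed Seed for shuffling, dropout and the validation carve-out.
#' @return The trained model with `$history` (`epoch`, `train_loss`,
#'   `val_loss`).
#' @export
train_model <- function(model, ds, seed = 42) {
  N <- n_windows(ds)
  if (N == 0) stop("empty dataset")
  cfg <- model$cfg
  nval <- round(N * cfg$val_fraction)
  val_idx <- if (nval > 0) with_seed(seed + 7L, sort(sample.int(N, nval))) else integer(0)
  tr_idx <- setdiff(seq_len(N), val_idx)
  xtr <- windows_to_cube(ds$x[tr_idx, , , drop = FALSE])
  ytr <- labels_to_internal(model, ds$y[tr_idx])
  if (length(val_idx)) {
    xval <- windows_to_cube(ds$x[val_idx, , , drop = FALSE])
    yval <- labels_to_internal(model, ds$y[val_idx])
  } else {
    xval <- array(0, c(dim(ds$x)[3], dim(ds$x)[2], 0))
    yval <- integer(0)
  }
  fit <- lstm_train_cpp(model$params, xtr, ytr, xval, yval,
                        as.integer(cfg$epochs), as.integer(cfg$batch_size),
                        cfg$learning_rate, cfg$l2, cfg$dropout,
                        as.integer(seed))
  model$params <- fit$params
  model$history <- data.frame(epoch = seq_len(cfg$epochs),
                              train_loss = fit$train_loss,
                              val_loss = fit$val_loss)
  model
}

#' Class probabilities for windows
#'
#' @param model Trained `posture_model`.
#' @param x N x window x 36 array or a `windowed_dataset`.
#' @return N x classes probability matrix (rows sum to 1), columns named by
#'   the external labels.
#' @export
predict_proba <- function(model, x) {
  if (inherits(x, "windowed_dataset")) x <- x$x
  p <- lstm_predict_cpp(model$params, windows_to_cube(x))
  colnames(p) <- as.character(model$label_map)
  p
}

#' Predicted labels for windows
#' @inheritParams predict_proba
#' @export
predict_label <- function(model, x) {
  p <- predict_proba(model, x)
  model$label_map[max.col(p, ties.method = "first")]
}

#' Metrics from a confusion matrix
#'
#' @param cm K x K count matrix, rows = truth, columns = prediction.
#' @return data.frame `label`, `precision`, `recall`, `f_score` plus the
#'   overall accuracy as attribute `accuracy`.
#' @export
metrics_from_confusion <- function(cm) {
  tp <- diag(cm)
  prec <- tp / pmax(1e-12, colSums(cm))
  rec <- tp / pmax(1e-12, rowSums(cm))
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  out <- data.frame(label = seq_len(nrow(cm)), precision = prec,
                    recall = rec, f_score = f)
  attr(out, "accuracy") <- sum(tp) / sum(cm)
  out
}

confusion_matrix <- function(truth, pred, classes) {
  cm <- matrix(0L, classes, classes,
               dimnames = list(truth = seq_len(classes),
                               pred = seq_len(classes)))
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' Repeated train/test evaluation
#'
#' To average out training stochasticity, the dataset is re-split
#' (`ratio`, seeded per repeat), a fresh model is built and trained, and
#' test metrics are computed; accuracies and per-class precision/recall/F
#' are averaged over the repeats and confusion counts are summed.
#'
#' @param ds Full `windowed_dataset`.
#' @param cfg A [model_config()].
#' @param repeats Number of repeats (default 5).
#' @param seeds Optional explicit repeat seeds (length `repeats`).
#' @param ratio Test fraction per split (default 0.2: the 4:1 split).
#' @param input_dim Features per frame.
#' @return Object of class `eval_report`: `accuracy` (mean), `per_class`
#'   (averaged), `confusion` (summed), `repeats` (per-run accuracies),
#'   `histories` (per-run loss curves), `final_val_loss` (first run).
#' @export
evaluate_repeats <- function(ds, cfg = model_config(), repeats = 5,
                             seeds = NULL, ratio = 0.2, input_dim = NULL) {
  if (repeats < 1) stop("repeats must be >= 1")
  if (is.null(seeds)) seeds <- 42L + seq_len(repeats) - 1L
  stopifnot(length(seeds) == repeats)
  if (is.null(input_dim)) input_dim <- dim(ds$x)[3]
  accs <- numeric(repeats)
  per_run <- vector("list", repeats)
  histories <- vector("list", repeats)
  confusion <- matrix(0L, cfg$classes, cfg$classes,
                      dimnames = list(truth = seq_len(cfg$classes),
                                      pred = seq_len(cfg$classes)))
  for (i in seq_len(repeats)) {
    sp <- split_dataset(ds, ratio = ratio, seed = seeds[i])
    model <- build_model(cfg, input_dim = input_dim, seed = seeds[i])
    model <- train_model(model, sp$train, seed = seeds[i])
    pred <- predict_label(model, sp$test)
    cm <- confusion_matrix(sp$test$y, pred, cfg$classes)
    confusion <- confusion + cm
    m <- metrics_from_confusion(cm)
    accs[i] <- attr(m, "accuracy")
    per_run[[i]] <- m
    histories[[i]] <- model$history
  }
  per_class <- per_run[[1]]
  if (repeats > 1) {
    for (cl in c("precision", "recall", "f_score")) {
      per_class[[cl]] <- rowMeans(vapply(per_run, function(m) m[[cl]],
                                         numeric(cfg$classes)))
    }
  }
  structure(list(accuracy = mean(accs), per_class = per_class,
                 confusion = confusion, repeats = accs,
                 histories = histories,
                 final_val_loss = utils::tail(histories[[1]]$val_loss, 1)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Posture recognition over %d repeat(s)\n", length(x$repeats)))
  cat(sprintf("  mean test accuracy: %.4f (runs: %s)\n", x$accuracy,
              paste(sprintf("%.4f", x$repeats), collapse = ", ")))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  class %d  P=%.4f R=%.4f F=%.4f\n", pc$label[i],
                pc$precision[i], pc$recall[i], pc$f_score[i]))
  }
  invisible(x)
}

#' Streaming window-by-window prediction
#'
#' Emits a prediction every `stride` frames over the trailing `window`
#' frames, after a warm-up of the first `window` frames. Per-prediction
#' wall-clock latency is logged for information only.
#'
#' @param model Trained `posture_model`.
#' @param features n x 36 per-frame feature matrix.
#' @param window,stride Window geometry (defaults 50/5).
#' @return data.frame `frame` (1-based index of the window end), `label`,
#'   `prob` (winning probability), `latency_ms`.
#' @export
predict_stream <- function(model, features, window = 50, stride = 5) {
  n <- nrow(features)
  if (n < window) {
    warning(sprintf("warm-up: only %d of %d frames buffered, no prediction yet",
                    n, window))
    return(data.frame(frame = integer(0), label = integer(0),
                      prob = numeric(0), latency_ms = numeric(0)))
  }
  ends <- seq(window, n, by = stride)
  out <- data.frame(frame = ends, label = NA_integer_,
                    prob = NA_real_, latency_ms = NA_real_)
  for (k in seq_along(ends)) {
    t0 <- proc.time()[["elapsed"]]
    x <- array(features[(ends[k] - window + 1):ends[k], , drop = FALSE],
               c(1, window, ncol(features)))
    p <- predict_proba(model, x)
    out$label[k] <- model$label_map[which.max(p)]
    out$prob[k] <- max(p)
    out$latency_ms[k] <- (proc.time()[["elapsed"]] - t0) * 1000
  }
  out
}
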