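# End-to-end pipeline: synthesize (or ingest) IMU streams, filter,
# integrate, drift-compensate, reconstruct posture, extract features,
# window, split, train and evaluate — with artifacts written to disk and
# stage timings logged.

#' Pipeline configuration
#'
#' All knobs of the end-to-end run in one validated list. `script_scale`
#' scales every session duration (1 = the full protocol; smaller values for
#' desk-size runs).
#'
#' @param out_dir Artifact directory (created if needed).
#' @param seed Generation seed for the synthetic session.
#' @param script_scale Duration multiplier of the session script.
#' @param height_mm Subject stature.
#' @param filtering_strength,drift_compensation_strength See [filter_config()].
#' @param gravity m/s^2.
#' @param sample_rate Hz.
#' @param accel_noise_density,gyro_noise_density Table of sensor noise; see
#'   [sensor_noise_model()].
#' @param window,stride Sliding-window geometry.
#' @param split_ratio Test fraction.
#' @param repeats Training repeats for the evaluation.
#' @param repeat_seeds Optional explicit seeds, length `repeats`.
#' @param model A [model_config()].
#' @param write_streams Also write the six filtered IMU CSV streams.
#' @export
pipeline_config <- function(out_dir = tempfile("imuposture_run_"),
                            seed = DEFAULT_SEED,
                            script_scale = 1,
                            height_mm = 1580,
                            filtering_strength = 0.5,
                            drift_compensation_strength = 0.2,
                            gravity = 9.81,
                            sample_rate = 100,
                            accel_noise_density = 300,
                            gyro_noise_density = 0.007,
                            window = 50, stride = 5,
                            split_ratio = 0.2,
                            repeats = 5,
                            repeat_seeds = NULL,
                            model = model_config(),
                            write_streams = FALSE) {
  cfg <- list(out_dir = out_dir, seed = seed, script_scale = script_scale,
              height_mm = height_mm,
              filtering_strength = filtering_strength,
              drift_compensation_strength = drift_compensation_strength,
              gravity = gravity, sample_rate = sample_rate,
              accel_noise_density = accel_noise_density,
              gyro_noise_density = gyro_noise_density,
              window = window, stride = stride, split_ratio = split_ratio,
              repeats = repeats, repeat_seeds = repeat_seeds,
              model = model, write_streams = write_streams)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Errors name the missing or invalid key.
#' @param cfg A list of configuration values.
#' @export
validate_pipeline_config <- function(cfg) {
  required <- c("out_dir", "seed", "script_scale", "height_mm",
                "filtering_strength", "drift_compensation_strength",
                "gravity", "sample_rate", "accel_noise_density",
                "gyro_noise_density", "window", "stride", "split_ratio",
                "repeats", "model")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("pipeline config misses key(s): ", paste(missing, collapse = ", "))
  }
  if (cfg$script_scale <= 0) stop("invalid config key 'script_scale': must be > 0")
  if (cfg$window <= 0 || cfg$stride <= 0) stop("invalid config key 'window'/'stride'")
  invisible(cfg)
}

#' Read / write pipeline configurations as JSON
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass_recursive(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- do.call(model_config, raw$model[names(raw$model) %in%
                                             names(formals(model_config))])
  raw$model <- model
  do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

# Cheap deterministic content hash (base R; provenance stamping only).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass_recursive(cfg), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

stage_msg <- function(name, t0) {
  message(sprintf("[%s] %.1f s", name, proc.time()[["elapsed"]] - t0))
}

#' Run the full pipeline
#'
#' synthesize -> filter -> integrate -> drift-compensate -> posture ->
#' features -> windows -> split/train/evaluate. Every artifact is stamped
#' with the configuration hash and seeds; stage timings go to `message()`.
#'
#' @param cfg A [pipeline_config()].
#' @return List: `report` ([evaluate_repeats()] result), `dataset`,
#'   `posture`, `trace`, `features`, `paths`, `config_hash`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  frame <- frame_convention(cfg$gravity)
  sk <- skeleton_from_height(cfg$height_mm)
  cal <- identity_calibration()
  noise <- sensor_noise_model(cfg$accel_noise_density, cfg$gyro_noise_density,
                              sample_rate = cfg$sample_rate)
  fcfg <- filter_config(cfg$filtering_strength, cfg$drift_compensation_strength)

  t0 <- proc.time()[["elapsed"]]
  trace <- build_session(table3_script(cfg$script_scale, cfg$sample_rate),
                         seed = cfg$seed)
  sim <- imu_from_motion(trace, sk, cal, noise, frame, seed = cfg$seed + 99L)
  stage_msg("synth", t0)

  t0 <- proc.time()[["elapsed"]]
  streams <- lapply(sim$streams, filter_stream, cfg = fcfg)
  stage_msg("filter", t0)

  t0 <- proc.time()[["elapsed"]]
  state_dfs <- list()
  for (tr in TRACKER_IDS) {
    tr1 <- sim$truth[[tr]][1, ]
    init <- tracker_state(q = c(tr1$qw, tr1$qx, tr1$qy, tr1$qz),
                          v = c(tr1$vx, tr1$vy, tr1$vz),
                          d = c(tr1$px, tr1$py, tr1$pz), t = tr1$t)
    states <- integrate_stream(streams[[tr]], init, noise = sensor_noise_none(),
                               frame = frame)
    states <- drift_compensate(states, reference_q = init$q, cfg = fcfg)
    state_dfs[[tr]] <- states_to_df(states, tracker_id = tr)
  }
  stage_msg("integrate", t0)

  t0 <- proc.time()[["elapsed"]]
  posture <- posture_from_states(state_dfs, cal, sk)
  stage_msg("posture", t0)

  t0 <- proc.time()[["elapsed"]]
  feats <- extract_features(state_dfs, cal, labels = trace$labels)
  ds <- sliding_windows(feats, trace$labels, cfg$window, cfg$stride)
  stage_msg("features", t0)

  t0 <- proc.time()[["elapsed"]]
  report <- evaluate_repeats(ds, cfg$model, repeats = cfg$repeats,
                             seeds = cfg$repeat_seeds,
                             ratio = cfg$split_ratio)
  stage_msg("train/eval", t0)

  paths <- list()
  t0 <- proc.time()[["elapsed"]]
  for (tr in TRACKER_IDS) {
    p <- file.path(cfg$out_dir, sprintf("states_%s.csv", tr))
    write_states_csv(state_dfs[[tr]], p)
    paths[[paste0("states_", tr)]] <- p
    if (isTRUE(cfg$write_streams)) {
      ps <- file.path(cfg$out_dir, sprintf("imu_%s.csv", tr))
      write_imu_csv(streams[[tr]], ps)
      paths[[paste0("imu_", tr)]] <- ps
    }
  }
  paths$bvh <- file.path(cfg$out_dir, "posture.bvh")
  export_bvh(sk, posture$angles, paths$bvh, frame_time = 1 / cfg$sample_rate)
  paths$labels <- file.path(cfg$out_dir, "labels.csv")
  utils::write.csv(data.frame(t = trace$t, label = trace$labels),
                   paths$labels, row.names = FALSE)
  paths$dataset <- file.path(cfg$out_dir, "dataset.rds")
  saveRDS(list(ds = ds, config_hash = hash, seed = cfg$seed), paths$dataset)
  paths$report <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(list(
    config_hash = hash, seed = cfg$seed,
    accuracy = report$accuracy, repeats = report$repeats,
    per_class = report$per_class, confusion = report$confusion,
    final_val_loss = report$final_val_loss
  ), paths$report, auto_unbox = TRUE, digits = NA)
  paths$confusion <- file.path(cfg$out_dir, "confusion.csv")
  utils::write.csv(report$confusion, paths$confusion)
  stage_msg("artifacts", t0)

  list(report = report, dataset = ds, posture = posture, trace = trace,
       features = feats, paths = paths, config_hash = hash)
}
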