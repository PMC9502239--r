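#' Run the preprocessing and activity-recognition front end
#'
#' Down-samples each raw recording to the analysis rate, cuts non-overlapping
#' windows within calendar days, computes per-subject adaptive thresholds
#' from each subject's first recorded day, and annotates every window as
#' static, dynamic-non-walk or walk-like.
#'
#' @param recordings list of `inertial_recording` objects (one or more per
#'   subject).
#' @param analysis_rate analysis sampling rate in Hz (default 20).
#' @param window_seconds window length in seconds (default 5).
#' @param band walking band in Hz.
#' @param power_floor minimum mean walking-band PSD.
#' @param utc_offset_hours fixed offset defining calendar days.
#' @return list with `windows` (all windows, all subjects), `annotations`
#'   (data.frame), `walk_windows` (the walk-like subset), `thresholds`.
#' @export
detect_walks <- function(recordings, analysis_rate = 20, window_seconds = 5,
                         band = c(0.6, 2), power_floor = 100,
                         utc_offset_hours = 0) {
  ws <- lapply(recordings, function(rec)
    segment_windows(downsample_recording(rec, analysis_rate),
                    window_seconds, utc_offset_hours,
                    day_origin = "absolute"))
  ws <- ws[vapply(ws, length, 1L) > 0L]
  windows <- rebase_days(bind_windows(ws))
  sids <- unique(windows$subject_id)
  thresholds <- lapply(sids, function(s)
    subject_thresholds(windows[windows$subject_id == s]))
  names(thresholds) <- sids
  ann <- annotate_windows(windows, thresholds, band, power_floor)
  list(windows = windows, annotations = ann,
       walk_windows = windows[ann$label == "walk_like"],
       thresholds = thresholds)
}

#' Serialize a window collection to CSV
#'
#' One row per window: `subject_id, day_index, start_time` followed by the
#' 6 x L sample values row-major (acc x,y,z then gyro x,y,z).
#'
#' @param windows an `event_windows` object.
#' @param path output CSV path.
#' @export
write_windows <- function(windows, path) {
  n <- length(windows)
  L <- dim(windows$samples)[2]
  vals <- t(matrix(windows$samples, 6L * L, n))
  colnames(vals) <- paste0("v", seq_len(6L * L))
  df <- cbind(data.frame(subject_id = windows$subject_id,
                         day_index = windows$day_index,
                         start_time = windows$start_time,
                         sample_rate = windows$sample_rate),
              as.data.frame(vals))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a window collection written by [write_windows()]
#'
#' @param path CSV path.
#' @return an `event_windows` object.
#' @export
read_windows <- function(path) {
  df <- utils::read.csv(path)
  n <- nrow(df)
  vals <- as.matrix(df[, grep("^v", names(df)), drop = FALSE])
  L <- ncol(vals) / 6L
  event_windows(df$subject_id, df$day_index, df$start_time,
                array(t(vals), dim = c(6L, L, n)), df$sample_rate[1])
}

#' Pipeline run configuration
#'
#' Flat configuration for the command-line pipeline; defaults are the method's standard
#' operating point (5-s windows at 20 Hz, 0.6-2 Hz walking band,
#' power floor 100, the default CNN shape, 10 training days).
#'
#' @param out_dir artifact directory.
#' @param input_dir directory of raw recording CSVs (for `ingest`/`detect`).
#' @param analysis_rate,window_seconds,band,power_floor front-end settings.
#' @param train_day_limit LOGO training day budget.
#' @param sensors `"both"`, `"acc"` or `"gyro"`.
#' @param cnn a `cnn_config`.
#' @param sim a `simulation_config` (for the `simulate` stage).
#' @param seed master seed; propagated to the CNN and simulator configs.
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir = "pdwear_out", input_dir = NULL,
                       analysis_rate = 20, window_seconds = 5,
                       band = c(0.6, 2), power_floor = 100,
                       train_day_limit = 10L, sensors = "both",
                       cnn = cnn_config(), sim = NULL, seed = 1L) {
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  cnn$seed <- as.integer(seed)
  sim$seed <- as.integer(seed)
  cfg <- list(out_dir = out_dir, input_dir = input_dir,
              analysis_rate = analysis_rate, window_seconds = window_seconds,
              band = band, power_floor = power_floor,
              train_day_limit = as.integer(train_day_limit),
              sensors = match.arg(sensors, c("both", "acc", "gyro")),
              cnn = cnn, sim = sim, seed = as.integer(seed))
  stopifnot(cfg$analysis_rate > 0, cfg$window_seconds > 0,
            length(cfg$band) == 2L, cfg$band[1] < cfg$band[2],
            cfg$power_floor >= 0, cfg$train_day_limit >= 1L)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat keys override [run_config()] defaults; nested `cnn:` and `sim:` maps
#' override the respective sub-configurations.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cnn <- do.call(cnn_config, y$cnn %||% list())
  sim <- do.call(simulation_config, y$sim %||% list())
  args <- y[setdiff(names(y), c("cnn", "sim"))]
  do.call(run_config, c(args, list(cnn = cnn, sim = sim)))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

write_manifest <- function(cfg, stage, counts = list()) {
  manifest <- list(stage = stage, seed = cfg$seed,
                   config_hash = config_hash(unclass(cfg)),
                   package_version = as.character(
                     utils::packageVersion("pdwear")),
                   counts = counts)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, producer) {
  p <- stage_path(cfg, name)
  if (!file.exists(p))
    stop("missing input '", name, "': run the '", producer, "' stage first")
  p
}

#' Run one pipeline stage
#'
#' Stages read and write artifacts under `cfg$out_dir` and are idempotent
#' given identical configuration and inputs: `simulate` writes raw recording
#' CSVs, a subjects table and ground-truth intervals; `ingest` validates raw
#' CSVs from `cfg$input_dir` into the artifact directory; `detect` runs the
#' activity-recognition front end and writes annotations and walk-like
#' windows; `features` writes the 35-column feature matrix; `train_cnn` runs
#' the LOGO cross-validation and saves per-fold models; `train_baselines`
#' fits the four comparison classifiers on shared folds; `evaluate` writes
#' event/daily accuracy reports and the walk-duration summary; `predict`
#' applies saved fold models to the walk-like windows.
#'
#' @param stage one of `"simulate", "ingest", "detect", "features",
#'   "train_cnn", "train_baselines", "evaluate", "predict"`.
#' @param cfg a `run_config`.
#' @return invisibly, a list of the artifacts written.
#' @export
run_stage <- function(stage = c("simulate", "ingest", "detect", "features",
                                "train_cnn", "train_baselines", "evaluate",
                                "predict"),
                      cfg = run_config()) {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    stage,
    simulate = {
      cohort <- simulate_cohort(cfg$sim)
      raw <- stage_path(cfg, "raw")
      dir.create(raw, showWarnings = FALSE)
      for (rec in cohort$recordings) {
        day <- floor(rec$timestamps[1] / 86400000)
        write_recording(rec, file.path(raw, sprintf("%s_day%d.csv",
                                                    rec$subject_id, day)))
      }
      utils::write.csv(cohort$subjects, stage_path(cfg, "subjects.csv"),
                       row.names = FALSE)
      utils::write.csv(cohort$truth, stage_path(cfg, "truth.csv"),
                       row.names = FALSE)
      write_manifest(cfg, stage,
                     list(recordings = length(cohort$recordings),
                          subjects = nrow(cohort$subjects)))
      list(raw = raw)
    },
    ingest = {
      if (is.null(cfg$input_dir)) stop("ingest: cfg$input_dir is not set")
      files <- list.files(cfg$input_dir, "\\.csv$", full.names = TRUE)
      if (!length(files)) stop("ingest: no CSV files in ", cfg$input_dir)
      raw <- stage_path(cfg, "raw")
      dir.create(raw, showWarnings = FALSE)
      n <- 0L
      for (f in files) {
        segs <- read_recording(f)
        for (k in seq_along(segs)) {
          if (length(segs[[k]]) == 0L) next
          n <- n + 1L
          write_recording(segs[[k]],
                          file.path(raw, sprintf("%s_seg%d.csv",
                                                 segs[[k]]$subject_id, k)))
        }
      }
      write_manifest(cfg, stage, list(segments = n))
      list(raw = raw)
    },
    detect = {
      raw <- require_artifact(cfg, "raw", "simulate/ingest")
      files <- list.files(raw, "\\.csv$", full.names = TRUE)
      recs <- lapply(files, function(f) {
        sid <- sub("_(day|seg).*$", "", basename(f))
        read_recording(f, subject_id = sid,
                       sample_rate = cfg$sim$sample_rate)[[1]]
      })
      det <- detect_walks(recs, cfg$analysis_rate, cfg$window_seconds,
                          cfg$band, cfg$power_floor)
      utils::write.csv(det$annotations, stage_path(cfg, "annotations.csv"),
                       row.names = FALSE)
      write_windows(det$walk_windows, stage_path(cfg, "walk_windows.csv"))
      write_manifest(cfg, stage, list(
        windows = length(det$windows),
        dynamic = sum(det$annotations$label != "static"),
        walk_like = sum(det$annotations$label == "walk_like")))
      list(annotations = stage_path(cfg, "annotations.csv"))
    },
    features = {
      w <- read_windows(require_artifact(cfg, "walk_windows.csv", "detect"))
      fm <- feature_matrix(w)
      utils::write.csv(fm, stage_path(cfg, "features.csv"), row.names = FALSE)
      write_manifest(cfg, stage, list(rows = nrow(fm)))
      list(features = stage_path(cfg, "features.csv"))
    },
    train_cnn = {
      w <- read_windows(require_artifact(cfg, "walk_windows.csv", "detect"))
      subjects <- utils::read.csv(require_artifact(cfg, "subjects.csv",
                                                   "simulate"))
      folds <- make_logo_folds(subjects, cfg$train_day_limit)
      logo <- run_logo_cv(w, folds, cfg$cnn, cfg$sensors)
      saveRDS(logo, stage_path(cfg, "logo_cnn.rds"))
      utils::write.csv(logo$predictions, stage_path(cfg, "predictions.csv"),
                       row.names = FALSE)
      write_manifest(cfg, stage, list(folds = length(folds$folds),
                                      events = nrow(logo$predictions)))
      list(model = stage_path(cfg, "logo_cnn.rds"))
    },
    train_baselines = {
      fm <- utils::read.csv(require_artifact(cfg, "features.csv", "features"))
      subjects <- utils::read.csv(require_artifact(cfg, "subjects.csv",
                                                   "simulate"))
      folds <- make_logo_folds(subjects, cfg$train_day_limit)
      specs <- lapply(c("logistic_regression", "random_forest",
                        "gradient_boosted_trees", "elastic_net"),
                      baseline_spec, seed = cfg$seed)
      tab <- evaluate_baselines(specs, fm, folds$diagnosis, folds)
      utils::write.csv(tab, stage_path(cfg, "baselines.csv"),
                       row.names = FALSE)
      write_manifest(cfg, stage, list(methods = nrow(tab)))
      list(baselines = stage_path(cfg, "baselines.csv"))
    },
    evaluate = {
      logo <- readRDS(require_artifact(cfg, "logo_cnn.rds", "train_cnn"))
      ann <- utils::read.csv(require_artifact(cfg, "annotations.csv",
                                              "detect"))
      w <- read_windows(stage_path(cfg, "walk_windows.csv"))
      report <- data.frame(
        subject_id = names(logo$subject_event_accuracy),
        event_accuracy = as.numeric(logo$subject_event_accuracy))
      daily_acc <- tapply(logo$daily$decided == logo$daily$truth,
                          logo$daily$subject_id, mean)
      report$daily_vote_accuracy <-
        as.numeric(daily_acc[report$subject_id])
      utils::write.csv(report, stage_path(cfg, "report_logo.csv"),
                       row.names = FALSE)
      has_holdout <- any(w$day_index >= 30 + min(w$day_index))
      if (has_holdout) {
        hold <- temporal_holdout_eval(logo, w)
        utils::write.csv(hold$events, stage_path(cfg, "report_holdout.csv"),
                         row.names = FALSE)
      }
      dur <- walk_duration_summary(ann, logo$folds$diagnosis,
                                   cfg$window_seconds)
      utils::write.csv(dur$daily, stage_path(cfg, "walk_durations.csv"),
                       row.names = FALSE)
      write_manifest(cfg, stage, list(subjects = nrow(report)))
      list(report = stage_path(cfg, "report_logo.csv"))
    },
    predict = {
      logo <- readRDS(require_artifact(cfg, "logo_cnn.rds", "train_cnn"))
      w <- read_windows(require_artifact(cfg, "walk_windows.csv", "detect"))
      preds <- NULL
      for (s in names(logo$models)) {
        sel <- w$subject_id == s
        if (any(sel))
          preds <- rbind(preds, predict_events(logo$models[[s]], w[sel]))
      }
      utils::write.csv(preds, stage_path(cfg, "predictions_all.csv"),
                       row.names = FALSE)
      utils::write.csv(daily_decisions(preds),
                       stage_path(cfg, "daily_decisions.csv"),
                       row.names = FALSE)
      write_manifest(cfg, stage, list(events = nrow(preds)))
      list(predictions = stage_path(cfg, "predictions_all.csv"))
    })
  invisible(out)
}
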