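# Pipeline entry points behind the command-line tool: simulate a labelled
# dataset, train the cascade (and optionally the baseline), and predict
# quality classes/levels for records or segment files.  Every run writes a
# reproducibility manifest (configuration hash, seeds, package version).

.run_manifest <- function(dir, config, extra = list()) {
  man <- c(list(
    package = "ecgsqc",
    version = as.character(utils::packageVersion("ecgsqc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = .spec_hash(config),
    seed = config$seed %||% NA),
    extra)
  jsonlite::write_json(man, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from JSON
#'
#' @param path JSON file with any of: `out_dir`, `seed`, `counts` (named
#'   per-class), `epochs`, `batch_size`, `initial_lr`, `format`
#'   (`"text"`/`"parquet"`), `train_baseline` (logical).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$counts)) cfg$counts <- unlist(cfg$counts)
  cfg
}

#' Simulate a labelled dataset to disk
#'
#' Generates a synthetic dataset from the configuration and writes it
#' together with a manifest recording seeds and class counts.  Deterministic
#' given the configuration: rerunning reproduces identical files.
#'
#' @param config List with `out_dir`, optional `seed` (default 1),
#'   `counts`, `format` (`"text"` writes `dataset.csv`; `"parquet"` the
#'   binary container) and any [dataset_spec()] range overrides.
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  seed <- config$seed %||% 1L
  spec_args <- config[intersect(names(config),
                                c("counts", "hr_range", "r_amp_range",
                                  "mild_ratio_range", "severe_ratio_range",
                                  "duration_range", "rr_jitter_frac"))]
  spec <- do.call(dataset_spec, c(spec_args, list(seed = seed)))
  ds <- generate_dataset(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- config$format %||% "text"
  if (fmt == "parquet") {
    write_dataset_container(ds, file.path(out_dir, "dataset"))
  } else {
    write_dataset_text(ds, file.path(out_dir, "dataset.csv"))
  }
  counts <- as.list(table(factor(ds$labels, quality_classes())))
  .run_manifest(out_dir, c(config, list(seed = seed)),
                list(n_segments = length(ds$segments),
                     class_counts = counts, format = fmt))
  invisible(out_dir)
}

#' Train the cascade (and optionally the baseline) from a dataset on disk
#'
#' @param config List with `dataset` (path to `dataset.csv` or a container
#'   directory), `out_dir`, optional `seed`, `epochs`, `batch_size`,
#'   `initial_lr`, `val_frac` and `train_baseline`.
#' @return Invisibly, the output directory with checkpoints
#'   (`subnetwork_type`, `subnetwork_motion_level`, `subnetwork_myo_level`,
#'   optionally `baseline`) and per-epoch training logs.
#' @export
run_train <- function(config) {
  ds_path <- config$dataset %||% stop("config$dataset is required")
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  ds <- .load_any_dataset(ds_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg <- train_config("cascaded",
                      initial_lr = config$initial_lr %||% NULL,
                      epochs = config$epochs %||% NULL,
                      batch_size = config$batch_size %||% 100L,
                      seed = config$seed %||% 1L)
  fit <- fit_cascade(ds, cfg, val_frac = config$val_frac %||% 0.1)
  for (nm in names(fit$subnetworks)) {
    save_network(fit$subnetworks[[nm]],
                 file.path(out_dir, paste0("subnetwork_", nm)))
    utils::write.csv(fit$histories[[nm]],
                     file.path(out_dir, paste0("history_", nm, ".csv")),
                     row.names = FALSE)
  }
  extra <- list(n_segments = length(ds$segments),
                epochs = cfg$epochs, batch_size = cfg$batch_size)
  if (isTRUE(config$train_baseline)) {
    bcfg <- train_config("baseline",
                         initial_lr = config$baseline_initial_lr %||% NULL,
                         epochs = config$epochs %||% NULL,
                         batch_size = config$batch_size %||% 100L,
                         seed = config$seed %||% 1L)
    bfit <- fit_baseline(ds, bcfg, val_frac = config$val_frac %||% 0.1)
    save_network(bfit$network, file.path(out_dir, "baseline"))
    utils::write.csv(bfit$history, file.path(out_dir, "history_baseline.csv"),
                     row.names = FALSE)
    extra$baseline <- TRUE
  }
  .run_manifest(out_dir, c(config, list(seed = cfg$seed)), extra)
  invisible(out_dir)
}

.load_any_dataset <- function(path) {
  if (dir.exists(path)) {
    if (file.exists(file.path(path, "segments.parquet"))) {
      return(read_dataset_container(path))
    }
    if (file.exists(file.path(path, "dataset.csv"))) {
      return(read_dataset_text(file.path(path, "dataset.csv")))
    }
    if (dir.exists(file.path(path, "dataset"))) {
      return(read_dataset_container(file.path(path, "dataset")))
    }
    stop("no dataset found under ", path)
  }
  if (!file.exists(path)) stop("dataset not found: ", path)
  read_dataset_text(path)
}

#' Predict quality classes for a record or segment file
#'
#' Accepts a WFDB record (resampled to 128 Hz, band-pass filtered and cut
#' into 4-s segments), a delimited-text signal (one sample per line, `# fs=`
#' header), or a segment CSV written by [write_dataset_text()].  Writes a
#' per-segment table of (segment index, class, level), an aggregated report
#' with the mixed-interference level of the whole input, and a manifest.
#'
#' @param config List with `model_dir` (checkpoints from [run_train()]),
#'   `input` (record path), `out_dir`, optional `lead` (WFDB channel name).
#' @return Invisibly, the per-segment prediction data frame.
#' @export
run_predict <- function(config) {
  model_dir <- config$model_dir %||% stop("config$model_dir is required")
  input <- config$input %||% stop("config$input is required")
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  nets <- lapply(c("type", "motion_level", "myo_level"), function(nm) {
    load_network(file.path(model_dir, paste0("subnetwork_", nm)))
  })
  segs <- .load_segments_for_prediction(input, config$lead %||% NULL)
  if (nrow(segs) == 0) {
    warning("input shorter than one 4-second segment; no predictions")
    preds <- data.frame(segment = integer(0), class = character(0),
                        level = character(0))
  } else {
    cls <- cascade_predict(segs, nets[[1]], nets[[2]], nets[[3]])
    preds <- data.frame(segment = seq_len(nrow(segs)), class = cls,
                        level = class_to_level(cls))
  }
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  agg <- if (nrow(preds) > 0) {
    resolve_mixed_interference(unique(preds$level))
  } else NA_character_
  .run_manifest(out_dir, config,
                list(n_segments = nrow(preds),
                     level_counts = if (nrow(preds) > 0) {
                       as.list(table(factor(preds$level, quality_levels())))
                     } else list(),
                     aggregated_level = agg))
  invisible(preds)
}

.load_segments_for_prediction <- function(input, lead = NULL) {
  if (file.exists(paste0(input, ".hea")) || grepl("\\.hea$", input)) {
    rec <- read_wfdb(input, lead = lead)
    x <- rec$signal[, 1]
    return(preprocess_record(x, rec$fs))
  }
  if (grepl("\\.csv$", input)) {
    return(segment_matrix(read_dataset_text(input)))
  }
  txt <- read_ecg_text(input)
  if (txt$fs == 128 && length(txt$samples) == ECG_SEG_SAMPLES) {
    return(matrix(txt$samples, nrow = 1))
  }
  preprocess_record(txt$samples, txt$fs)
}
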