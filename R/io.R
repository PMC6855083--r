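# Dataset persistence: a portable binary array container (Apache
# Arrow/Parquet: samples, labels and event tables) plus a plain
# delimited-text export (one segment per row).

#' Write / read a dataset in the binary array container
#'
#' Stores the n x 512 sample matrix, labels, R heights and the event table
#' as Parquet files in a directory, with a JSON manifest.  Requires the
#' `arrow` package.
#'
#' @param ds An `ecg_dataset`.
#' @param dir Container directory (created if needed).
#' @return `write_dataset_container()`: invisibly, `dir`;
#'   `read_dataset_container()`: the reconstructed `ecg_dataset` (the
#'   generator spec is restored; per-segment clean traces are not stored
#'   and segments are returned with samples, label, R height and events).
#' @export
write_dataset_container <- function(ds, dir) {
  if (!inherits(ds, "ecg_dataset")) stop("ds must be an ecg_dataset")
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for the binary dataset container")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$segments)
  samples <- as.data.frame(segment_matrix(ds))
  names(samples) <- sprintf("s%03d", seq_len(ECG_SEG_SAMPLES))
  meta <- data.frame(
    index = seq_len(n),
    label = ds$labels,
    label_code = class_to_code(ds$labels),
    r_height_mv = vapply(ds$segments, `[[`, numeric(1), "r_height_mv"))
  events <- do.call(rbind, lapply(seq_len(n), function(i) {
    evs <- ds$segments[[i]]$events
    if (length(evs) == 0) return(NULL)
    data.frame(index = i,
               kind = vapply(evs, `[[`, character(1), "kind"),
               start_s = vapply(evs, `[[`, numeric(1), "start_s"),
               end_s = vapply(evs, `[[`, numeric(1), "end_s"),
               peak_ratio = vapply(evs, `[[`, numeric(1), "peak_ratio"))
  }))
  if (is.null(events)) {
    events <- data.frame(index = integer(0), kind = character(0),
                         start_s = numeric(0), end_s = numeric(0),
                         peak_ratio = numeric(0))
  }
  arrow::write_parquet(cbind(meta, samples), file.path(dir, "segments.parquet"))
  arrow::write_parquet(events, file.path(dir, "events.parquet"))
  spec <- ds$spec
  jsonlite::write_json(
    list(n_segments = n, fs = ECG_FS, segment_samples = ECG_SEG_SAMPLES,
         class_counts = as.list(table(factor(ds$labels, quality_classes()))),
         spec = if (!is.null(spec)) unclass(spec)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset_container
#' @export
read_dataset_container <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for the binary dataset container")
  }
  seg_df <- as.data.frame(arrow::read_parquet(file.path(dir, "segments.parquet")))
  ev_df <- as.data.frame(arrow::read_parquet(file.path(dir, "events.parquet")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sample_cols <- grep("^s[0-9]+$", names(seg_df))
  segments <- lapply(seq_len(nrow(seg_df)), function(i) {
    evs <- ev_df[ev_df$index == seg_df$index[i], , drop = FALSE]
    events <- lapply(seq_len(nrow(evs)), function(j) {
      noise_event(evs$kind[j], evs$start_s[j], evs$end_s[j],
                  evs$peak_ratio[j])
    })
    structure(list(samples = as.numeric(seg_df[i, sample_cols]),
                   fs = ECG_FS,
                   r_height_mv = seg_df$r_height_mv[i],
                   events = events,
                   true_class = seg_df$label[i]),
              class = "ecg_segment")
  })
  spec <- man$spec
  if (!is.null(spec)) {
    spec <- dataset_spec(counts = unlist(spec$counts),
                         hr_range = unlist(spec$hr_range),
                         r_amp_range = unlist(spec$r_amp_range),
                         mild_ratio_range = unlist(spec$mild_ratio_range),
                         severe_ratio_range = unlist(spec$severe_ratio_range),
                         duration_range = unlist(spec$duration_range),
                         rr_jitter_frac = spec$rr_jitter_frac,
                         seed = spec$seed)
  }
  structure(list(segments = segments, labels = seg_df$label, spec = spec),
            class = "ecg_dataset")
}

#' Export / import a dataset as delimited text
#'
#' One segment per row: `label`, `r_height_mv`, then the 512 sample values,
#' comma-separated with a header line.
#'
#' @param ds An `ecg_dataset`.
#' @param path Output file.
#' @return `write_dataset_text()`: invisibly, `path`;
#'   `read_dataset_text()`: an `ecg_dataset` (without event tables, which
#'   the text format does not carry).
#' @export
write_dataset_text <- function(ds, path) {
  if (!inherits(ds, "ecg_dataset")) stop("ds must be an ecg_dataset")
  df <- data.frame(label = ds$labels,
                   r_height_mv = vapply(ds$segments, `[[`, numeric(1),
                                        "r_height_mv"))
  df <- cbind(df, as.data.frame(segment_matrix(ds)))
  names(df)[-(1:2)] <- sprintf("s%03d", seq_len(ECG_SEG_SAMPLES))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_text
#' @export
read_dataset_text <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_cols <- grep("^s[0-9]+$", names(df))
  segments <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(samples = as.numeric(df[i, sample_cols]), fs = ECG_FS,
                   r_height_mv = df$r_height_mv[i], events = list(),
                   true_class = df$label[i]),
              class = "ecg_segment")
  })
  structure(list(segments = segments, labels = df$label, spec = NULL),
            class = "ecg_dataset")
}
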