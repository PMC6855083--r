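# Two-stage cascade inference and evaluation metrics: stage 1 assigns the
# interference type (low / motion / myoelectric); motion segments are routed
# to the motion-level subnetwork and myoelectric segments to the
# myoelectric-level subnetwork.  Metrics follow the one-vs-rest
# sensitivity/specificity definitions with overall accuracy = trace/total.

#' Route cascade stage probabilities to a five-class prediction
#'
#' Pure routing logic, usable with stubbed probabilities: the stage-1 argmax
#' over (low, motion, myoelectric) decides which (if any) stage-2 output is
#' consulted; ties break to the lowest class index.
#'
#' @param stage1 Numeric matrix n x 3 of type probabilities (columns: low,
#'   motion, myoelectric), or a length-3 vector.
#' @param motion Numeric matrix n x 2 of (mild, severe) motion-level
#'   probabilities; only rows routed to motion are consulted.
#' @param myo Numeric matrix n x 2 of (mild, severe) myoelectric-level
#'   probabilities.
#' @return Character vector of [quality_classes()] predictions.
#' @export
#' @examples
#' cascade_route(c(0.1, 0.8, 0.1), motion = c(0.3, 0.7))
cascade_route <- function(stage1, motion = NULL, myo = NULL) {
  if (is.vector(stage1)) stage1 <- matrix(stage1, nrow = 1)
  if (is.vector(motion)) motion <- matrix(motion, nrow = 1)
  if (is.vector(myo)) myo <- matrix(myo, nrow = 1)
  n <- nrow(stage1)
  type <- max.col(stage1, ties.method = "first")
  out <- character(n)
  out[type == 1L] <- "low"
  im <- which(type == 2L)
  if (length(im) > 0) {
    if (is.null(motion)) stop("motion-level probabilities required")
    sel <- if (nrow(motion) == n) motion[im, , drop = FALSE] else motion
    sev <- max.col(sel, ties.method = "first") == 2L
    out[im] <- ifelse(sev, "severe_motion", "mild_motion")
  }
  iy <- which(type == 3L)
  if (length(iy) > 0) {
    if (is.null(myo)) stop("myoelectric-level probabilities required")
    sel <- if (nrow(myo) == n) myo[iy, , drop = FALSE] else myo
    sev <- max.col(sel, ties.method = "first") == 2L
    out[iy] <- ifelse(sev, "severe_myo", "mild_myo")
  }
  out
}

#' Cascade prediction for raw segments
#'
#' Runs the two-stage cascade on 512-sample segments: stage-2 subnetworks
#' are only invoked for the segments stage 1 routes to them.
#'
#' @param segments Numeric matrix (one 512-sample segment per row), a
#'   single segment vector, or an `ecg_dataset`.
#' @param type_net,motion_net,myo_net Trained `ecg_network` subnetworks
#'   with 3, 2 and 2 classes.
#' @param prepared Optional precomputed [prepare_inputs()] tensors.
#' @return Character vector of predicted [quality_classes()].
#' @export
cascade_predict <- function(segments, type_net, motion_net, myo_net,
                            prepared = NULL) {
  for (net in list(type_net, motion_net, myo_net)) {
    if (!inherits(net, "ecg_network") || !isTRUE(net$trained)) {
      stop("cascade_predict requires three trained ecg_network subnetworks")
    }
  }
  if (!identical(type_net$arch$n_classes, 3L) ||
      !identical(motion_net$arch$n_classes, 2L) ||
      !identical(myo_net$arch$n_classes, 2L)) {
    stop("subnetworks must have 3, 2 and 2 output classes")
  }
  if (is.null(prepared)) prepared <- prepare_inputs(segments)
  n <- nrow(prepared$raw)
  p1 <- .forward_chunked(type_net, prepared$spec, prepared$raw)
  type <- max.col(p1, ties.method = "first")
  out <- character(n)
  out[type == 1L] <- "low"
  for (stage in list(list(idx = which(type == 2L), net = motion_net,
                          cls = c("mild_motion", "severe_motion")),
                     list(idx = which(type == 3L), net = myo_net,
                          cls = c("mild_myo", "severe_myo")))) {
    if (length(stage$idx) == 0) next
    p2 <- .forward_chunked(stage$net,
                           prepared$spec[, , stage$idx, drop = FALSE],
                           prepared$raw[stage$idx, , drop = FALSE])
    out[stage$idx] <- stage$cls[max.col(p2, ties.method = "first")]
  }
  out
}

#' @export
predict.ecg_cascade <- function(object, newdata, type = c("class", "level"),
                                prepared = NULL, ...) {
  type <- match.arg(type)
  cls <- cascade_predict(newdata, object$subnetworks$type,
                         object$subnetworks$motion_level,
                         object$subnetworks$myo_level, prepared = prepared)
  if (type == "level") class_to_level(cls) else cls
}

#' @export
predict.ecg_baseline_fit <- function(object, newdata,
                                     type = c("class", "level"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ecg_dataset")) newdata <- segment_matrix(newdata)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  raw <- t(apply(newdata, 1, .zscore_signal))
  p <- .forward_chunked(object$network, NULL, raw)
  cls <- code_to_class(max.col(p, ties.method = "first") - 1L)
  if (type == "level") class_to_level(cls) else cls
}

#' Confusion matrix of true vs predicted classes
#'
#' @param truth,predicted Character vectors of class labels.
#' @param classes Class vocabulary fixing row/column order (default: the
#'   classes present, in [quality_classes()] order if applicable).
#' @return Integer K x K matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (is.null(classes)) {
    present <- unique(c(truth, predicted))
    classes <- if (all(present %in% quality_classes())) {
      intersect(quality_classes(), present)
    } else sort(present)
  }
  tab <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

# one-vs-rest reduction: TP, FN, FP, TN for a class index/name
.ovr_counts <- function(cm, class) {
  if (is.character(class)) class <- match(class, rownames(cm))
  if (is.na(class) || class < 1 || class > nrow(cm)) stop("unknown class")
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' One-vs-rest per class: `Se = TP / (TP + FN)`, `Sp = TN / (FP + TN)`;
#' overall accuracy is `trace / total`.  A zero denominator yields `NA`
#' (reported as missing, never as 0).
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param class Class name or index for the one-vs-rest reduction.
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' cm <- matrix(c(9, 2, 1, 8), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' sensitivity(cm, "a"); specificity(cm, "a"); overall_accuracy(cm)
sensitivity <- function(cm, class) {
  k <- .ovr_counts(cm, class)
  if (k["tp"] + k["fn"] == 0) return(NA_real_)
  unname(k["tp"] / (k["tp"] + k["fn"]))
}

#' @rdname sensitivity
#' @export
specificity <- function(cm, class) {
  k <- .ovr_counts(cm, class)
  if (k["fp"] + k["tn"] == 0) return(NA_real_)
  unname(k["tn"] / (k["fp"] + k["tn"]))
}

#' @rdname sensitivity
#' @export
overall_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) return(NA_real_)
  sum(diag(cm)) / tot
}

#' Per-record accuracy table
#'
#' @param truth,predicted Class labels per segment.
#' @param record Record identifier per segment.
#' @return Data frame with columns `record`, `n` and `accuracy`, sorted by
#'   record id; empty groups are excluded with a warning.
#' @export
per_record_accuracy <- function(truth, predicted, record) {
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(record))
  keep <- !is.na(record)
  if (any(!keep)) warning("segments with missing record id were excluded")
  truth <- truth[keep]; predicted <- predicted[keep]; record <- record[keep]
  ids <- sort(unique(record))
  rows <- lapply(ids, function(id) {
    sel <- record == id
    data.frame(record = id, n = sum(sel),
               accuracy = mean(truth[sel] == predicted[sel]))
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' @param truth,predicted Class labels per segment.
#' @param record Optional record ids for a per-record accuracy table.
#' @param classes Optional class vocabulary.
#' @return An `eval_report`: confusion matrix, per-class Se/Sp/Ac, overall
#'   accuracy and the optional per-record table.
#' @export
eval_report <- function(truth, predicted, record = NULL, classes = NULL) {
  cm <- confusion_matrix(truth, predicted, classes)
  cls <- rownames(cm)
  per_class <- data.frame(
    class = cls,
    sensitivity = vapply(cls, function(k) sensitivity(cm, k), numeric(1)),
    specificity = vapply(cls, function(k) specificity(cm, k), numeric(1)),
    accuracy = vapply(cls, function(k) {
      v <- .ovr_counts(cm, k)
      (v["tp"] + v["tn"]) / sum(v)
    }, numeric(1)),
    row.names = NULL)
  rep <- list(confusion = cm, per_class = per_class,
              overall_accuracy = overall_accuracy(cm),
              per_record = if (!is.null(record)) {
                per_record_accuracy(truth, predicted, record)
              })
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\nPer-class metrics (one-vs-rest):\n")
  pc <- x$per_class
  pc[, -1] <- round(pc[, -1], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("\nOverall accuracy: %.*f\n", digits, x$overall_accuracy))
  if (!is.null(x$per_record)) {
    cat("\nPer-record accuracy:\n")
    print(x$per_record, row.names = FALSE)
  }
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the confusion matrix as tab-separated text and the metrics as
#' JSON.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$confusion, file.path(dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(per_class = report$per_class,
         overall_accuracy = report$overall_accuracy,
         per_record = report$per_record),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, dataframe = "rows")
  invisible(dir)
}
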