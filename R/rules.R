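# Rule-based five-class quality labelling for 4-second dynamic ECG segments.
#
# A segment is labelled by the interference that dominates it: a noise kind
# whose total duration inside the 4-s window exceeds 2 s becomes the label,
# and its severity is graded against the clean R-wave height (mild below half
# the R height, severe at or above half).

#' Five interference classes of dynamic ECG signal quality
#'
#' The five-class vocabulary used throughout the package, in the fixed order
#' that also defines the integer serialization codes 0--4:
#' `low` (0), `mild_myo` (1), `severe_myo` (2), `mild_motion` (3),
#' `severe_motion` (4).
#'
#' @return Character vector of the five class names in code order.
#' @export
#' @examples
#' quality_classes()
quality_classes <- function() {
  c("low", "mild_myo", "severe_myo", "mild_motion", "severe_motion")
}

#' Three clinical quality levels
#'
#' Severity-ordered levels: `low` < `mild` < `severe`.  Low-interference
#' segments are usable for full morphological diagnosis, mild ones for
#' heart-rate / HRV measurement, severe ones should be discarded.
#'
#' @return Ordered factor levels as a character vector.
#' @export
quality_levels <- function() {
  c("low", "mild", "severe")
}

#' Convert quality classes to integer codes and back
#'
#' @param x Character vector of class names (see [quality_classes()]).
#' @return `class_to_code()`: integer codes 0--4; `code_to_class()`:
#'   character class names.
#' @export
#' @examples
#' class_to_code(c("low", "severe_motion"))
#' code_to_class(c(0L, 4L))
class_to_code <- function(x) {
  m <- match(x, quality_classes())
  if (anyNA(m)) stop("unknown quality class: ", paste(x[is.na(m)], collapse = ", "))
  m - 1L
}

#' @rdname class_to_code
#' @param code Integer codes in 0--4.
#' @export
code_to_class <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 4L)) stop("quality class codes must lie in 0..4")
  quality_classes()[code + 1L]
}

#' Describe one interference event within a segment
#'
#' An event is a contiguous interval of one interference kind with a peak
#' amplitude expressed relative to the segment's clean R-wave height.
#'
#' @param kind `"motion"` (electrode motion artifact, < 7 Hz) or
#'   `"myoelectric"` (EMG noise, 30 Hz up to Nyquist).
#' @param start_s,end_s Event bounds in seconds within `[0, 4]`,
#'   `start_s < end_s`.
#' @param peak_ratio Maximum absolute noise amplitude divided by the R-wave
#'   height (dimensionless, >= 0).
#' @return A `noise_event` object (named list).
#' @export
#' @examples
#' noise_event("motion", 0.5, 3.0, peak_ratio = 0.8)
noise_event <- function(kind = c("motion", "myoelectric"), start_s, end_s,
                        peak_ratio) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(start_s), is.numeric(end_s), is.numeric(peak_ratio))
  if (!(start_s >= 0 && start_s < end_s && end_s <= 4)) {
    stop("event bounds must satisfy 0 <= start_s < end_s <= 4")
  }
  if (peak_ratio < 0) stop("peak_ratio must be >= 0")
  structure(list(kind = kind, start_s = start_s, end_s = end_s,
                 peak_ratio = peak_ratio),
            class = "noise_event")
}

#' Label a segment from its interference events
#'
#' Applies the dominance rules: a noise kind whose total duration exceeds
#' 2 s (half the window) becomes the label; its grade is `severe` when the
#' kind's maximum peak ratio reaches half the clean R-wave height
#' (`peak_ratio >= 0.5`), `mild` otherwise.  With no dominating kind the
#' segment is `low`.  If both kinds dominate (rare in practice), the longer
#' total duration wins; an exact tie goes to motion (fixed tie-break).
#'
#' @param events List of [noise_event()] objects (possibly empty).
#' @param r_height_mv Clean R-wave height in mV (> 0), the amplitude
#'   reference of the severity rule.
#' @return One of [quality_classes()].
#' @export
#' @examples
#' label_segment(list(), 1)
#' label_segment(list(noise_event("myoelectric", 0.5, 3.5, 0.7)), 1)
label_segment <- function(events, r_height_mv) {
  if (!is.numeric(r_height_mv) || length(r_height_mv) != 1L || r_height_mv <= 0) {
    stop("r_height_mv must be a single positive number")
  }
  if (length(events) == 0L) return("low")
  if (inherits(events, "noise_event")) events <- list(events)
  kinds <- vapply(events, function(e) e$kind, character(1))
  durs <- vapply(events, function(e) e$end_s - e$start_s, numeric(1))
  peaks <- vapply(events, function(e) e$peak_ratio, numeric(1))

  total <- function(k) sum(durs[kinds == k])
  dom <- c(motion = total("motion"), myoelectric = total("myoelectric"))
  dom <- dom[dom > 2]
  if (length(dom) == 0L) return("low")
  # both kinds dominating: longer total wins, exact tie -> motion
  kind <- names(dom)[which.max(dom)]  # which.max keeps first on ties; order is motion first
  peak <- max(peaks[kinds == kind])
  severe <- peak >= 0.5
  if (kind == "motion") {
    if (severe) "severe_motion" else "mild_motion"
  } else {
    if (severe) "severe_myo" else "mild_myo"
  }
}

#' Map a five-class label to its clinical level
#'
#' @param x Character vector of quality classes.
#' @return Character vector of levels (`"low"`, `"mild"`, `"severe"`).
#' @export
#' @examples
#' class_to_level(c("low", "mild_motion", "severe_myo"))
class_to_level <- function(x) {
  m <- c(low = "low", mild_myo = "mild", severe_myo = "severe",
         mild_motion = "mild", severe_motion = "severe")
  out <- unname(m[x])
  if (anyNA(out)) stop("unknown quality class: ", paste(x[is.na(out)], collapse = ", "))
  out
}

#' Aggregate mixed interference levels for clinical review
#'
#' When a stretch of recording contains several predicted levels -- even if
#' the higher one lasts under 2 s -- the highest severity present is
#' assigned, so that clinicians never under-read interference.
#'
#' @param levels_present Non-empty character vector (or set) of quality
#'   levels.
#' @return The maximum-severity level present.
#' @export
#' @examples
#' resolve_mixed_interference(c("low", "mild"))
#' resolve_mixed_interference(c("mild", "severe"))
resolve_mixed_interference <- function(levels_present) {
  levels_present <- unique(as.character(levels_present))
  if (length(levels_present) == 0L) stop("levels_present must be non-empty")
  ord <- match(levels_present, quality_levels())
  if (anyNA(ord)) {
    stop("unknown quality level: ",
         paste(levels_present[is.na(ord)], collapse = ", "))
  }
  quality_levels()[max(ord)]
}
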