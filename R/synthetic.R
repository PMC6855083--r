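# Synthetic dynamic-ECG generator: labelled 4-second, 128 Hz, 512-sample
# single-lead segments with controlled clean morphology, motion artifacts
# (slow irregular waves below 7 Hz) and myoelectric noise (30 Hz up to the
# 64 Hz Nyquist limit), at controlled noise-to-R-wave amplitude ratios.

ECG_FS <- 128L          # segment sampling rate, Hz
ECG_SEG_SAMPLES <- 512L # 4 s at 128 Hz
ECG_SEG_SECONDS <- 4

#' Parameters of the clean PQRST beat template
#'
#' One cardiac cycle is modelled as a sum of five Gaussians (one per wave:
#' P, Q, R, S, T), repeated at jittered RR intervals -- the classic
#' dynamical-template approach to synthetic ECG.  Wave amplitudes in
#' `wave_params` are expressed relative to the R wave and are scaled by
#' `r_amplitude_mv`, so the baseline-to-R-peak height of the clean signal is
#' `r_amplitude_mv` millivolts.
#'
#' @param heart_rate_bpm Heart rate in beats/min (40--180; default 60).
#' @param r_amplitude_mv Baseline-to-R-peak height in mV (>= 0; default 1).
#'   Clinically plausible single-lead ECG amplitudes span 0.05--5 mV.
#' @param wave_params Data frame with columns `wave`, `amplitude` (relative
#'   to R), `width` (Gaussian sigma, s) and `offset` (s, from the R peak).
#' @param rr_jitter_frac Fractional standard deviation of beat-to-beat (RR)
#'   interval variability (default 0.05).
#' @return A `clean_ecg_params` object.
#' @export
#' @examples
#' clean_ecg_params(heart_rate_bpm = 75)
clean_ecg_params <- function(heart_rate_bpm = 60,
                             r_amplitude_mv = 1.0,
                             wave_params = default_wave_params(),
                             rr_jitter_frac = 0.05) {
  stopifnot(is.numeric(heart_rate_bpm), length(heart_rate_bpm) == 1L,
            is.numeric(r_amplitude_mv), length(r_amplitude_mv) == 1L,
            is.data.frame(wave_params))
  if (heart_rate_bpm <= 0) stop("heart_rate_bpm must be positive")
  if (heart_rate_bpm < 40 || heart_rate_bpm > 180) {
    stop("heart_rate_bpm must lie in [40, 180]")
  }
  if (r_amplitude_mv < 0) stop("r_amplitude_mv must be >= 0")
  need <- c("wave", "amplitude", "width", "offset")
  if (!all(need %in% names(wave_params))) {
    stop("wave_params needs columns: ", paste(need, collapse = ", "))
  }
  if (any(wave_params$width <= 0)) stop("wave widths must be positive")
  if (rr_jitter_frac < 0) stop("rr_jitter_frac must be >= 0")
  structure(list(heart_rate_bpm = heart_rate_bpm,
                 r_amplitude_mv = r_amplitude_mv,
                 wave_params = wave_params,
                 rr_jitter_frac = rr_jitter_frac),
            class = "clean_ecg_params")
}

#' @rdname clean_ecg_params
#' @export
default_wave_params <- function() {
  data.frame(
    wave      = c("P",     "Q",     "R",    "S",     "T"),
    amplitude = c(0.15,   -0.10,    1.00,  -0.20,    0.30),
    width     = c(0.025,   0.010,   0.012,  0.012,   0.050),
    offset    = c(-0.200, -0.048,   0.000,  0.036,   0.300),
    stringsAsFactors = FALSE
  )
}

#' Generate one clean 4-second ECG segment
#'
#' @param params A [clean_ecg_params()] object.
#' @param seed Integer seed; the same seed reproduces the segment exactly.
#' @return An `ecg_segment`: list with `samples` (512 values, mV),
#'   `fs` (128), `r_height_mv` (ground-truth clean R height), `events`
#'   (empty list) and `true_class` (`"low"`).
#' @export
#' @examples
#' seg <- generate_clean_segment(clean_ecg_params(), seed = 1)
#' range(seg$samples)
generate_clean_segment <- function(params, seed) {
  if (!inherits(params, "clean_ecg_params")) {
    stop("params must be a clean_ecg_params object")
  }
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  rr <- 60 / params$heart_rate_bpm
  # R-peak times covering the window plus margins so edge beats are partial
  n_beats <- ceiling((ECG_SEG_SECONDS + 2) / rr) + 2L
  gaps <- rr * (1 + stats::rnorm(n_beats - 1L, 0, params$rr_jitter_frac))
  gaps <- pmax(gaps, 0.25 * rr)
  t_r <- stats::runif(1, -rr, 0) + c(0, cumsum(gaps))

  t <- (seq_len(ECG_SEG_SAMPLES) - 1L) / ECG_FS
  x <- numeric(ECG_SEG_SAMPLES)
  wp <- params$wave_params
  for (tr in t_r) {
    for (k in seq_len(nrow(wp))) {
      mu <- tr + wp$offset[k]
      # skip waves entirely outside the window (5 sigma)
      if (mu < -5 * wp$width[k] || mu > ECG_SEG_SECONDS + 5 * wp$width[k]) next
      x <- x + wp$amplitude[k] * exp(-(t - mu)^2 / (2 * wp$width[k]^2))
    }
  }
  x <- x * params$r_amplitude_mv

  structure(list(samples = x, fs = ECG_FS,
                 r_height_mv = params$r_amplitude_mv,
                 events = list(), true_class = "low"),
            class = "ecg_segment")
}

# Band-limit a series by zeroing FFT bins outside [f_lo, f_hi] Hz.
# Exact on the discrete frequency grid; DC is excluded unless f_lo <= 0.
.fft_bandmask <- function(x, f_lo, f_hi, fs = ECG_FS) {
  n <- length(x)
  k <- 0:(n - 1L)
  freq <- pmin(k, n - k) * fs / n   # absolute frequency of each bin
  keep <- freq >= f_lo & freq <= f_hi
  if (!any(keep)) keep[2L] <- TRUE  # degenerate short series: keep lowest bin
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

.scale_to_peak <- function(x, peak) {
  m <- max(abs(x))
  if (m == 0) return(x)
  x * (peak / m)
}

#' Generate a motion-artifact waveform
#'
#' Motion artifacts from electrode--skin contact changes appear as irregular
#' abrupt waves confined below 7 Hz.  They are realized as an
#' amplitude-modulated random walk (slow bursts) band-limited to
#' 0.25--6.5 Hz in the frequency domain, then scaled so the maximum absolute
#' amplitude equals `peak_amp_mv` exactly.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param peak_amp_mv Peak absolute amplitude in mV (>= 0; 0 gives zeros).
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration_s * 128)` samples.
#' @export
#' @examples
#' w <- generate_motion_artifact(3, 0.5, seed = 1)
#' max(abs(w))
generate_motion_artifact <- function(duration_s, peak_amp_mv, seed) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (peak_amp_mv < 0) stop("peak_amp_mv must be >= 0")
  n <- as.integer(round(duration_s * ECG_FS))
  if (peak_amp_mv == 0) return(numeric(n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  walk <- cumsum(stats::rnorm(n))
  walk <- walk - mean(walk)
  # slow burst envelope (<= 0.5 Hz content) keeps the artifact irregular
  env <- .fft_bandmask(cumsum(stats::rnorm(n)), 0, 0.5)
  env <- 0.35 + 0.65 * (abs(env) / max(abs(env), .Machine$double.eps))
  x <- .fft_bandmask(walk * env, 0.25, 6.5)
  .scale_to_peak(x, peak_amp_mv)
}

#' Generate a myoelectric (EMG) noise waveform
#'
#' Skeletal-muscle noise occupies roughly 30--300 Hz; sampled at 128 Hz only
#' the 30 Hz--Nyquist (64 Hz) part of that band survives, so the noise is
#' realized as Gaussian noise band-limited to 30--63 Hz, scaled so the
#' maximum absolute amplitude equals `peak_amp_mv` exactly.
#'
#' @inheritParams generate_motion_artifact
#' @return Numeric vector of `round(duration_s * 128)` samples.
#' @export
#' @examples
#' w <- generate_myoelectric_noise(2.5, 0.3, seed = 2)
#' length(w)
generate_myoelectric_noise <- function(duration_s, peak_amp_mv, seed) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (peak_amp_mv < 0) stop("peak_amp_mv must be >= 0")
  n <- as.integer(round(duration_s * ECG_FS))
  if (peak_amp_mv == 0) return(numeric(n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  x <- .fft_bandmask(stats::rnorm(n), 30, 63)
  .scale_to_peak(x, peak_amp_mv)
}

#' Add interference events to a clean segment
#'
#' Each event's noise realization is scaled so its maximum absolute
#' amplitude equals `peak_ratio * r_height_mv` and added only inside the
#' event's time span.  Events must be pairwise non-overlapping (within a
#' 4-s window, distinct interference patterns essentially never coexist, and
#' overlapping same-kind events would break the per-event amplitude
#' contract).
#'
#' @param clean An `ecg_segment` from [generate_clean_segment()].
#' @param events List of [noise_event()] objects.
#' @param seed Integer seed for the noise realizations.
#' @return An `ecg_segment` with the events recorded and
#'   `true_class = label_segment(events, r_height_mv)`.
#' @export
#' @examples
#' seg <- generate_clean_segment(clean_ecg_params(), seed = 1)
#' noisy <- compose_segment(seg, list(noise_event("motion", 0.5, 3, 0.8)),
#'                          seed = 2)
#' noisy$true_class
compose_segment <- function(clean, events, seed) {
  if (!inherits(clean, "ecg_segment")) stop("clean must be an ecg_segment")
  if (inherits(events, "noise_event")) events <- list(events)
  if (!all(vapply(events, inherits, logical(1), "noise_event"))) {
    stop("events must be a list of noise_event objects")
  }
  if (length(events) >= 2L) {
    for (i in seq_len(length(events) - 1L)) {
      for (j in (i + 1L):length(events)) {
        if (events[[i]]$start_s < events[[j]]$end_s &&
            events[[j]]$start_s < events[[i]]$end_s) {
          stop("overlapping noise events are not supported")
        }
      }
    }
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ev_seeds <- sample.int(.Machine$integer.max - 1L, max(1L, length(events)))

  x <- clean$samples
  for (i in seq_along(events)) {
    e <- events[[i]]
    n_ev <- as.integer(round((e$end_s - e$start_s) * ECG_FS))
    if (n_ev == 0L) next
    peak <- e$peak_ratio * clean$r_height_mv
    noise <- switch(e$kind,
      motion      = generate_motion_artifact(n_ev / ECG_FS, peak, ev_seeds[i]),
      myoelectric = generate_myoelectric_noise(n_ev / ECG_FS, peak, ev_seeds[i]))
    i0 <- as.integer(round(e$start_s * ECG_FS))
    idx <- (i0 + 1L):min(i0 + n_ev, ECG_SEG_SAMPLES)
    x[idx] <- x[idx] + noise[seq_along(idx)]
  }
  structure(list(samples = x, fs = ECG_FS,
                 r_height_mv = clean$r_height_mv,
                 events = events,
                 true_class = label_segment(events, clean$r_height_mv)),
            class = "ecg_segment")
}

#' Specify a synthetic labelled dataset
#'
#' Defaults mirror the composition of clinical Holter corpora: twice as many
#' low-interference segments as each noisy class (a 2:1:1:1:1 ratio), heart
#' rates 50--120 bpm, R heights 0.5--2 mV, mild noise peaking at 0.2--0.4 of
#' the R height and severe noise at 0.6--0.9, event durations 2.2--4 s (a
#' label-defining event must exceed 2 s).
#'
#' @param counts Named integer vector of per-class segment counts, names
#'   from [quality_classes()].
#' @param hr_range,r_amp_range Sampling ranges for heart rate (bpm) and
#'   R amplitude (mV).
#' @param mild_ratio_range Peak-ratio range for mild classes; must lie
#'   strictly inside (0, 0.5).
#' @param severe_ratio_range Peak-ratio range for severe classes; must lie
#'   in [0.5, Inf).
#' @param duration_range Event duration range in seconds; lower bound > 2 so
#'   the event defines the label.
#' @param rr_jitter_frac RR-interval jitter fraction.
#' @param seed Master seed; per-segment seeds are derived from it.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(counts = c(low = 200, mild_myo = 100, severe_myo = 100,
                                    mild_motion = 100, severe_motion = 100),
                         hr_range = c(50, 120),
                         r_amp_range = c(0.5, 2.0),
                         mild_ratio_range = c(0.2, 0.4),
                         severe_ratio_range = c(0.6, 0.9),
                         duration_range = c(2.2, 4.0),
                         rr_jitter_frac = 0.05,
                         seed = 1L) {
  cls <- quality_classes()
  full <- stats::setNames(integer(5L), cls)
  if (is.null(names(counts))) {
    if (length(counts) != 5L) stop("unnamed counts must have length 5")
    names(counts) <- cls
  }
  if (!all(names(counts) %in% cls)) {
    stop("counts names must be among: ", paste(cls, collapse = ", "))
  }
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0L)) stop("counts must be >= 0")
  stopifnot(length(hr_range) == 2L, length(r_amp_range) == 2L,
            length(mild_ratio_range) == 2L, length(severe_ratio_range) == 2L,
            length(duration_range) == 2L)
  if (!(mild_ratio_range[1] > 0 && mild_ratio_range[2] < 0.5 &&
        mild_ratio_range[1] <= mild_ratio_range[2])) {
    stop("mild_ratio_range must lie strictly inside (0, 0.5)")
  }
  if (!(severe_ratio_range[1] >= 0.5 &&
        severe_ratio_range[1] <= severe_ratio_range[2])) {
    stop("severe_ratio_range must lie in [0.5, Inf)")
  }
  if (duration_range[1] <= 2 || duration_range[2] > 4 ||
      duration_range[1] > duration_range[2]) {
    stop("duration_range must lie in (2, 4]")
  }
  structure(list(counts = full, hr_range = hr_range, r_amp_range = r_amp_range,
                 mild_ratio_range = mild_ratio_range,
                 severe_ratio_range = severe_ratio_range,
                 duration_range = duration_range,
                 rr_jitter_frac = rr_jitter_frac,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Generate a labelled synthetic dataset
#'
#' @param spec A [dataset_spec()].
#' @return An `ecg_dataset`: list with `segments` (list of `ecg_segment`),
#'   `labels` (character vector of true classes) and `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(dataset_spec(counts = c(low = 4, mild_myo = 2,
#'   severe_myo = 2, mild_motion = 2, severe_motion = 2), seed = 7))
#' table(ds$labels)
generate_dataset <- function(spec) {
  if (!inherits(spec, "dataset_spec")) stop("spec must be a dataset_spec")
  total <- sum(spec$counts)
  labels <- rep(names(spec$counts), times = spec$counts)
  if (total == 0L) {
    return(structure(list(segments = list(), labels = character(0),
                          spec = spec), class = "ecg_dataset"))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  seg_seeds <- sample.int(.Machine$integer.max - 1L, total)

  segments <- vector("list", total)
  for (i in seq_len(total)) {
    segments[[i]] <- .generate_labelled_segment(labels[i], spec, seg_seeds[i])
    stopifnot(identical(segments[[i]]$true_class, labels[i]))
  }
  structure(list(segments = segments, labels = labels, spec = spec),
            class = "ecg_dataset")
}

.generate_labelled_segment <- function(label, spec, seed) {
  set.seed(seed)
  hr <- stats::runif(1, spec$hr_range[1], spec$hr_range[2])
  r_amp <- stats::runif(1, spec$r_amp_range[1], spec$r_amp_range[2])
  dur <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
  start <- stats::runif(1, 0, ECG_SEG_SECONDS - dur)
  ratio_mild <- stats::runif(1, spec$mild_ratio_range[1], spec$mild_ratio_range[2])
  ratio_severe <- stats::runif(1, spec$severe_ratio_range[1], spec$severe_ratio_range[2])
  sub <- sample.int(.Machine$integer.max - 1L, 2L)

  params <- clean_ecg_params(heart_rate_bpm = hr, r_amplitude_mv = r_amp,
                             rr_jitter_frac = spec$rr_jitter_frac)
  clean <- generate_clean_segment(params, seed = sub[1L])
  if (label == "low") return(clean)

  kind <- if (label %in% c("mild_motion", "severe_motion")) "motion" else "myoelectric"
  ratio <- if (label %in% c("mild_motion", "mild_myo")) ratio_mild else ratio_severe
  ev <- noise_event(kind, start, start + dur, ratio)
  compose_segment(clean, list(ev), seed = sub[2L])
}

#' Extract the sample matrix of a dataset
#'
#' @param ds An `ecg_dataset`.
#' @return Numeric matrix, one row per segment, 512 columns.
#' @export
segment_matrix <- function(ds) {
  if (!inherits(ds, "ecg_dataset")) stop("ds must be an ecg_dataset")
  if (length(ds$segments) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = ECG_SEG_SAMPLES))
  }
  t(vapply(ds$segments, function(s) s$samples, numeric(ECG_SEG_SAMPLES)))
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat("Synthetic dynamic-ECG dataset:", length(x$segments),
      "segments (4 s, 128 Hz)\n")
  if (length(x$labels)) print(table(factor(x$labels, quality_classes())))
  invisible(x)
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("ecg_segment: 512 samples @ 128 Hz, R height %.3g mV, class %s, %d event(s)\n",
              x$r_height_mv, x$true_class, length(x$events)))
  invisible(x)
}

# Preserve the caller's RNG state across seeded generators.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
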