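# Preprocessing: band-pass filtering (0.5--40 Hz, second-order Butterworth),
# resampling to the 128 Hz working rate, and non-overlapping 4-second
# windowing into 512-sample segments.

#' Band-pass filter specification
#'
#' The preprocessing filter removes baseline drift below 0.5 Hz and
#' high-frequency noise above 40 Hz.  It is realized as a cascade of a
#' second-order Butterworth high-pass and a second-order Butterworth
#' low-pass.  `ZERO_PHASE` applies the cascade forward--backward (no phase
#' distortion, squared magnitude response; the offline default); `CAUSAL`
#' applies a single forward pass (streaming parity).
#'
#' @param order Filter order of each section (default 2).
#' @param highpass_cutoff_hz High-pass cutoff in Hz (default 0.5).
#' @param lowpass_cutoff_hz Low-pass cutoff in Hz (default 40).
#' @param phase_mode `"zero_phase"` or `"causal"`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 2L, highpass_cutoff_hz = 0.5,
                        lowpass_cutoff_hz = 40,
                        phase_mode = c("zero_phase", "causal")) {
  phase_mode <- match.arg(phase_mode)
  if (!(highpass_cutoff_hz > 0 && highpass_cutoff_hz < lowpass_cutoff_hz)) {
    stop("need 0 < highpass_cutoff_hz < lowpass_cutoff_hz")
  }
  structure(list(order = as.integer(order),
                 highpass_cutoff_hz = highpass_cutoff_hz,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 phase_mode = phase_mode),
            class = "filter_spec")
}

#' Band-pass filter an ECG series
#'
#' @param samples Numeric voltage series (mV).
#' @param fs Sampling rate in Hz; must exceed twice the low-pass cutoff.
#' @param spec A [filter_spec()].
#' @return Filtered series of the same length.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:511) / 128)
#' y <- bandpass_filter(x, 128)
bandpass_filter <- function(samples, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  if (spec$lowpass_cutoff_hz >= fs / 2) {
    stop("lowpass cutoff must be below the Nyquist frequency fs/2")
  }
  n <- length(samples)
  if (n < 3L * spec$order) stop("series too short for the filter order")
  hp <- signal::butter(spec$order, spec$highpass_cutoff_hz / (fs / 2), "high")
  lp <- signal::butter(spec$order, spec$lowpass_cutoff_hz / (fs / 2), "low")
  apply1 <- function(flt, x) {
    if (spec$phase_mode == "zero_phase") {
      # forward-backward with reflection padding to suppress edge transients
      np <- min(n - 1L, 3L * ceiling(fs / spec$highpass_cutoff_hz / 4))
      np <- max(np, 9L)
      np <- min(np, n - 1L)
      xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
      yp <- rev(signal::filter(flt, rev(signal::filter(flt, xp))))
      yp[(np + 1L):(np + n)]
    } else {
      as.numeric(signal::filter(flt, x))
    }
  }
  apply1(lp, apply1(hp, samples))
}

#' Resample a series to 128 Hz
#'
#' Polyphase rational resampling (e.g. 360 to 128 Hz uses the ratio 16/45).
#' Only downsampling (or identity) is supported; frequencies below the
#' 64 Hz output Nyquist are preserved.
#'
#' @param samples Numeric voltage series.
#' @param fs_in Input sampling rate in Hz (>= 128).
#' @return Series of length `round(length(samples) * 128 / fs_in)`.
#' @export
#' @examples
#' length(resample_to_128(numeric(648000), 360))
resample_to_128 <- function(samples, fs_in) {
  if (fs_in < 128) stop("upsampling to 128 Hz is not supported (fs_in < 128)")
  n_out <- as.integer(round(length(samples) * 128 / fs_in))
  if (fs_in == 128) return(samples)
  if (length(samples) == 0L) return(numeric(0))
  ratio <- 128 / fs_in
  # rational approximation p/q of the rate ratio
  q0 <- round(fs_in)
  g <- .gcd(128L, as.integer(q0))
  p <- 128L / g
  q <- as.integer(q0) / g
  y <- as.numeric(signal::resample(samples, p, q))
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Cut a 128 Hz record into non-overlapping 4-second segments
#'
#' @param samples Numeric series sampled at 128 Hz.
#' @param fs Sampling rate; must be 128.
#' @return Numeric matrix with one 512-sample segment per row
#'   (`floor(length(samples) / 512)` rows); the trailing remainder is
#'   dropped.
#' @export
#' @examples
#' nrow(segment_record(numeric(230400)))
segment_record <- function(samples, fs = 128) {
  if (fs != 128) stop("segment_record expects fs = 128")
  k <- length(samples) %/% ECG_SEG_SAMPLES
  if (k == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = ECG_SEG_SAMPLES))
  }
  matrix(samples[seq_len(k * ECG_SEG_SAMPLES)], nrow = k,
         ncol = ECG_SEG_SAMPLES, byrow = TRUE)
}

#' Full raw-record preprocessing pipeline
#'
#' Resamples to 128 Hz, band-pass filters (0.5--40 Hz) and windows into
#' 512-sample segments.
#'
#' @param samples Raw voltage series.
#' @param fs_in Input sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Matrix of segments as in [segment_record()].
#' @export
preprocess_record <- function(samples, fs_in, spec = filter_spec()) {
  x <- resample_to_128(samples, fs_in)
  x <- bandpass_filter(x, 128, spec)
  segment_record(x)
}

#' Read a WFDB record
#'
#' Minimal reader for WFDB header (`.hea`) plus signal (`.dat`) files in
#' format 212 (packed 12-bit, the MIT-BIH Arrhythmia encoding) or format 16
#' (16-bit little-endian).  Digital values are converted to millivolts via
#' each channel's gain and baseline.
#'
#' @param record Path to the record (with or without the `.hea` extension).
#' @param lead Optional lead (signal description) to select, e.g. `"MLII"`;
#'   by default all channels are returned.
#' @return List with `fs` (Hz), `signal` (matrix, one column per channel, in
#'   mV), `leads` (channel descriptions) and `record` (record name).
#' @export
read_wfdb <- function(record, lead = NULL) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- sub("/.*$", "", top[1])
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_

  sig <- lapply(lines[1 + seq_len(n_sig)], .parse_wfdb_signal_line)
  files <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(files) != 1L) stop("multi-file WFDB records are not supported")
  fmt <- unique(vapply(sig, `[[`, numeric(1), "format"))
  if (length(fmt) != 1L) stop("mixed signal formats are not supported")
  dat_path <- file.path(dirname(hea), files)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)

  raw_bytes <- readBin(dat_path, "raw", file.info(dat_path)$size)
  adc <- .decode_wfdb(raw_bytes, fmt, n_sig)
  if (!is.na(n_samp) && nrow(adc) > n_samp) adc <- adc[seq_len(n_samp), , drop = FALSE]

  mv <- adc
  for (j in seq_len(n_sig)) {
    mv[, j] <- (adc[, j] - sig[[j]]$baseline) / sig[[j]]$gain
  }
  leads <- vapply(sig, `[[`, character(1), "description")
  colnames(mv) <- leads
  if (!is.null(lead)) {
    hit <- which(leads == lead)
    if (length(hit) == 0L) {
      stop("lead '", lead, "' not found; available: ",
           paste(leads, collapse = ", "))
    }
    mv <- mv[, hit[1L], drop = FALSE]
    leads <- lead
  }
  list(fs = fs, signal = mv, leads = leads, record = rec_name)
}

.parse_wfdb_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  file <- f[1]
  fmt <- as.numeric(sub("x.*$|:.*$|\\+.*$", "", f[2]))
  gain_field <- if (length(f) >= 3) f[3] else "200"
  gain_part <- sub("/.*$", "", gain_field)
  baseline <- NA_real_
  if (grepl("\\(", gain_part)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_part))
    gain_part <- sub("\\(.*$", "", gain_part)
  }
  gain <- as.numeric(gain_part)
  if (is.na(gain) || gain == 0) gain <- 200
  adczero <- if (length(f) >= 6) as.numeric(f[6]) else 0
  if (is.na(baseline)) baseline <- adczero
  description <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  list(file = file, format = fmt, gain = gain, baseline = baseline,
       description = description)
}

.decode_wfdb <- function(bytes, fmt, n_sig) {
  if (fmt == 16) {
    v <- readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    n <- length(v) %/% n_sig
    matrix(v[seq_len(n * n_sig)], ncol = n_sig, byrow = TRUE)
  } else if (fmt == 212) {
    b <- as.integer(bytes)
    n_tri <- length(b) %/% 3L
    i <- 3L * (seq_len(n_tri) - 1L)
    s1 <- b[i + 1L] + bitwShiftL(bitwAnd(b[i + 2L], 15L), 8L)
    s2 <- b[i + 3L] + bitwShiftL(bitwAnd(bitwShiftR(b[i + 2L], 4L), 15L), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    n <- length(v) %/% n_sig
    matrix(v[seq_len(n * n_sig)], ncol = n_sig, byrow = TRUE)
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
}

#' Write a WFDB record
#'
#' Counterpart of [read_wfdb()] for formats 16 and 212; used to exchange
#' small records with other WFDB tools.
#'
#' @param record Output path (without extension).
#' @param signal Matrix of voltages in mV, one column per channel.
#' @param fs Sampling rate in Hz.
#' @param leads Channel descriptions.
#' @param gain ADC units per mV (default 200).
#' @param fmt Signal format, 16 or 212.
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(record, signal, fs, leads = colnames(signal),
                       gain = 200, fmt = 16) {
  signal <- as.matrix(signal)
  n_sig <- ncol(signal)
  if (is.null(leads)) leads <- paste0("ch", seq_len(n_sig))
  adc <- round(signal * gain)
  rec <- basename(record)
  hea <- paste0(record, ".hea")
  dat <- paste0(record, ".dat")
  hdr <- sprintf("%s %d %g %d", rec, n_sig, fs, nrow(signal))
  sig_lines <- sprintf("%s.dat %d %g(0)/mV %d 0 0 0 0 %s",
                       rec, as.integer(fmt),
                       gain, if (fmt == 212) 12L else 16L, leads)
  writeLines(c(hdr, sig_lines), hea)
  v <- as.integer(t(adc))
  if (fmt == 16) {
    writeBin(v, dat, size = 2L, endian = "little")
  } else if (fmt == 212) {
    if (length(v) %% 2L == 1L) v <- c(v, 0L)
    v <- ifelse(v < 0L, v + 4096L, v)
    a <- v[seq(1L, length(v), 2L)]
    b <- v[seq(2L, length(v), 2L)]
    bytes <- as.raw(rbind(bitwAnd(a, 255L),
                          bitwOr(bitwAnd(bitwShiftR(a, 8L), 15L),
                                 bitwShiftL(bitwAnd(bitwShiftR(b, 8L), 15L), 4L)),
                          bitwAnd(b, 255L)))
    writeBin(as.vector(bytes), dat)
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  invisible(hea)
}

#' Read / write a delimited-text ECG series
#'
#' One sample per line; a comment header carries the sampling rate
#' (`# fs=128`).
#'
#' @param path File path.
#' @return `read_ecg_text()`: list with `samples` and `fs`.
#' @export
read_ecg_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  fs <- 128
  m <- regmatches(hdr, regexpr("fs\\s*=\\s*[0-9.]+", hdr))
  if (length(m) > 0) fs <- as.numeric(sub("fs\\s*=\\s*", "", m[[1]]))
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  if (anyNA(vals)) stop("non-numeric sample values in ", path)
  list(samples = vals, fs = fs)
}

#' @rdname read_ecg_text
#' @param samples Numeric voltage series (mV).
#' @param fs Sampling rate in Hz.
#' @export
write_ecg_text <- function(samples, path, fs = 128) {
  writeLines(c(sprintf("# fs=%g", fs), format(samples, digits = 10,
                                              scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
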