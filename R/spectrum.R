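# Time-frequency representation of a 512-sample segment: short-time Fourier
# transform with a 16-point symmetric Hamming window, hop 8, zero-padded
# 512-point FFT frames -> a 257 x 63 log-magnitude matrix (0.25 Hz per
# frequency bin, 62.5 ms per time column).

STFT_WIN <- 16L
STFT_HOP <- 8L
STFT_NFFT <- 512L
STFT_EPS <- 1e-10

#' Short-time Fourier spectrogram of a 4-second segment
#'
#' Frames of 16 samples (symmetric Hamming window) advance by 8 samples
#' (50% overlap), giving `floor((512 - 8) / 8) = 63` frames; each frame is
#' zero-padded to a 512-point FFT, so 257 one-sided frequency rows cover
#' 0--64 Hz at 0.25 Hz resolution.  Values are `log10(|X| + 1e-10)`.
#'
#' @param samples Numeric vector of exactly 512 voltage samples (128 Hz).
#' @return An `ecg_spectrogram`: 257 x 63 numeric matrix with attributes
#'   `freq_resolution_hz` (0.25) and `frame_hop_s` (8/128).
#' @export
#' @examples
#' dim(stft_spectrum(sin(2 * pi * 16 * (0:511) / 128)))
stft_spectrum <- function(samples) {
  if (length(samples) != ECG_SEG_SAMPLES) {
    stop("stft_spectrum expects exactly 512 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) stop("samples must be finite")
  n_frames <- (ECG_SEG_SAMPLES - STFT_HOP) %/% STFT_HOP  # 63
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(STFT_WIN - 1L)) / (STFT_WIN - 1L))
  frames <- matrix(0, nrow = STFT_NFFT, ncol = n_frames)
  for (f in seq_len(n_frames)) {
    i0 <- (f - 1L) * STFT_HOP
    frames[seq_len(STFT_WIN), f] <- samples[i0 + seq_len(STFT_WIN)] * w
  }
  spec <- stats::mvfft(frames)[seq_len(STFT_NFFT / 2L + 1L), , drop = FALSE]
  out <- log10(Mod(spec) + STFT_EPS)
  structure(out, class = c("ecg_spectrogram", class(out)),
            freq_resolution_hz = 128 / STFT_NFFT,
            frame_hop_s = STFT_HOP / 128)
}

#' Standardize a spectrogram to zero mean and unit variance
#'
#' Applied per segment before the spectrogram enters the network.  A
#' near-zero variance (constant matrix) yields an all-zero output.
#'
#' @param spec Spectrogram matrix (any finite numeric matrix).
#' @return Matrix of the same shape with mean 0 and (sample) SD 1.
#' @export
standardize_spectrogram <- function(spec) {
  if (!all(is.finite(spec))) stop("spectrogram values must be finite")
  mu <- mean(spec)
  sdev <- stats::sd(as.vector(spec))
  if (!is.finite(sdev) || sdev < 1e-8) {
    out <- spec
    out[] <- 0
    return(out)
  }
  (spec - mu) / sdev
}

# Per-segment z-scoring of the raw 512-sample trace (network input
# conditioning for the time-domain branch).
.zscore_signal <- function(x) {
  sdev <- stats::sd(x)
  if (!is.finite(sdev) || sdev < 1e-8) return(rep(0, length(x)))
  (x - mean(x)) / sdev
}

#' Build standardized network input tensors from segments
#'
#' @param segments Matrix with one 512-sample segment per row, or an
#'   `ecg_dataset`.
#' @return List with `spec` (257 x 63 x n array of standardized
#'   spectrograms) and `raw` (n x 512 matrix of z-scored signals).
#' @export
prepare_inputs <- function(segments) {
  if (inherits(segments, "ecg_dataset")) segments <- segment_matrix(segments)
  if (is.vector(segments)) segments <- matrix(segments, nrow = 1)
  n <- nrow(segments)
  spec <- array(0, dim = c(257L, 63L, n))
  raw <- matrix(0, nrow = n, ncol = ECG_SEG_SAMPLES)
  for (i in seq_len(n)) {
    spec[, , i] <- standardize_spectrogram(stft_spectrum(segments[i, ]))
    raw[i, ] <- .zscore_signal(segments[i, ])
  }
  list(spec = spec, raw = raw)
}

#' Export a spectrogram as delimited text
#'
#' @param spec Spectrogram matrix.
#' @param path Output path (tab-separated, one frequency row per line).
#' @export
write_spectrogram_text <- function(spec, path) {
  utils::write.table(unclass(spec), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
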