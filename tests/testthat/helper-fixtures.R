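# Shared fixtures: tiny datasets, spectral power helpers, closed-form
# parameter counting (the independent oracle for the engine's count).

tiny_counts <- function(n = 4L) {
  c(low = n, mild_myo = n, severe_myo = n, mild_motion = n, severe_motion = n)
}

tiny_dataset <- function(n = 4L, seed = 11L) {
  generate_dataset(dataset_spec(counts = tiny_counts(n), seed = seed))
}

# fraction of periodogram power at frequencies in [f_lo, f_hi], fs = 128
power_fraction <- function(x, f_lo, f_hi, fs = 128) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  sum(p[freq >= f_lo & freq <= f_hi]) / sum(p)
}

# periodogram spectral centroid (Hz)
spectral_centroid <- function(x, fs = 128) {
  n <- length(x)
  half <- seq_len(floor(n / 2) + 1L)
  p <- Mod(stats::fft(x))[half]^2
  freq <- (half - 1L) * fs / n
  sum(freq * p) / sum(p)
}

# closed-form trainable-parameter count from layer arithmetic, independent
# of the network builder: conv kernels + biases, BN scale + shift, dense
# weights + biases
count_params_closed_form <- function(n_blocks, channels, kind,
                                     n_classes = NULL) {
  conv_bn <- function(k, cin, cout) (k * cin * cout + cout) + 2 * cout
  branch <- function(k) {
    total <- 0
    cin <- 1
    for (s in 1:3) {
      for (b in seq_len(n_blocks[s])) {
        total <- total + conv_bn(k, cin, channels[s])
        cin <- channels[s]
      }
    }
    total + (cin * 32 + 32)  # 1x1 tail conv, no BN
  }
  # spatial sizes after floor pooling
  dims_cnn1 <- c(257 %/% 4 %/% 4 %/% 4, 63 %/% 2 %/% 2 %/% 4)
  len_cnn2 <- 512 %/% 4 %/% 4 %/% 4
  head <- function(fc_in, k_out) {
    (fc_in * 128 + 128) + (128 * k_out + k_out)
  }
  if (kind == "baseline") {
    branch(3) + head(32 * len_cnn2, 5)
  } else {
    branch(9) + branch(3) + head(32 * prod(dims_cnn1) + 32 * len_cnn2,
                                 n_classes)
  }
}

# deterministic pure sinusoid segment at 128 Hz
sinusoid_segment <- function(freq_hz, n = 512L, fs = 128) {
  sin(2 * pi * freq_hz * (0:(n - 1L)) / fs)
}
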