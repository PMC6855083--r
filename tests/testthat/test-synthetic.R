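# Synthetic generator: clean PQRST morphology, band-limited noise,
# composition, labelling round-trip and the amplitude contract.

test_that("clean segment has the expected R-peak count and height", {
  seg <- generate_clean_segment(clean_ecg_params(heart_rate_bpm = 60,
                                                 r_amplitude_mv = 1.0),
                                seed = 1)
  expect_length(seg$samples, 512)
  expect_identical(seg$true_class, "low")
  expect_length(seg$events, 0)
  # peak-count oracle: strict local maxima above half R height with >= 0.25 s
  # separation
  x <- seg$samples
  locmax <- which(x[2:511] > x[1:510] & x[2:511] > x[3:512] &
                    x[2:511] > 0.5) + 1L
  if (length(locmax) > 1) {
    keep <- c(TRUE, diff(locmax) >= 0.25 * 128)
    locmax <- locmax[keep]
  }
  expect_gte(length(locmax), 3)
  expect_lte(length(locmax), 5)
  expect_lt(abs(max(x) - 1.0), 0.05)
})

test_that("peak count tracks heart rate", {
  for (hr in c(48, 90, 150)) {
    seg <- generate_clean_segment(clean_ecg_params(heart_rate_bpm = hr),
                                  seed = 3)
    x <- seg$samples
    locmax <- which(x[2:511] > x[1:510] & x[2:511] > x[3:512] &
                      x[2:511] > 0.5) + 1L
    expected <- 4 * hr / 60
    expect_lte(abs(length(locmax) - expected), 1.5)
  }
})

test_that("zero R amplitude yields an all-zero segment", {
  seg <- generate_clean_segment(clean_ecg_params(r_amplitude_mv = 0), seed = 2)
  expect_identical(seg$samples, rep(0, 512))
})

test_that("clean generation is seed-deterministic and leaves the RNG alone", {
  set.seed(99)
  before <- .Random.seed
  a <- generate_clean_segment(clean_ecg_params(), seed = 7)
  expect_identical(.Random.seed, before)
  b <- generate_clean_segment(clean_ecg_params(), seed = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_clean_segment(clean_ecg_params(), seed = 8)
  expect_false(identical(a$samples, c$samples))
})

test_that("invalid clean parameters are rejected", {
  expect_error(clean_ecg_params(heart_rate_bpm = 30), "40")
  expect_error(clean_ecg_params(r_amplitude_mv = -1), ">= 0")
  wp <- default_wave_params(); wp$width[1] <- 0
  expect_error(clean_ecg_params(wave_params = wp), "width")
})

test_that("motion artifact is low-frequency with exact peak amplitude", {
  w <- generate_motion_artifact(3, 0.5, seed = 1)
  expect_length(w, 384)
  expect_equal(max(abs(w)), 0.5, tolerance = 1e-6)
  expect_lt(1 - power_fraction(w, 0, 7), 0.05)
})

test_that("myoelectric noise is confined to the 30-63 Hz band", {
  w <- generate_myoelectric_noise(2.5, 0.3, seed = 2)
  expect_length(w, 320)
  expect_equal(max(abs(w)), 0.3, tolerance = 1e-6)
  expect_gte(power_fraction(w, 30, 63), 0.90)
})

test_that("noise generators scale linearly and handle zero amplitude", {
  w1 <- generate_motion_artifact(2, 0.25, seed = 5)
  w2 <- generate_motion_artifact(2, 0.50, seed = 5)
  expect_equal(w2, 2 * w1, tolerance = 1e-12)
  expect_identical(generate_motion_artifact(1, 0, seed = 1), numeric(128))
  expect_identical(generate_myoelectric_noise(1, 0, seed = 1), numeric(128))
  m1 <- generate_myoelectric_noise(2, 0.2, seed = 1)
  m2 <- generate_myoelectric_noise(2, 0.2, seed = 2)
  expect_length(m2, length(m1))
  expect_false(identical(m1, m2))
  expect_error(generate_motion_artifact(0, 1, 1), "positive")
  expect_error(generate_myoelectric_noise(-1, 1, 1), "positive")
})

test_that("spectral separation between the two noise kinds holds across seeds", {
  cents_mot <- vapply(1:100, function(s) {
    spectral_centroid(generate_motion_artifact(2, 1, seed = s))
  }, numeric(1))
  cents_myo <- vapply(1:100, function(s) {
    spectral_centroid(generate_myoelectric_noise(2, 1, seed = s))
  }, numeric(1))
  expect_lt(mean(cents_mot), 7)
  expect_gt(mean(cents_myo), 7)
  expect_true(all(cents_mot < cents_myo))
})

test_that("compose_segment honours the labelling rules", {
  clean <- generate_clean_segment(clean_ecg_params(), seed = 1)
  expect_identical(compose_segment(clean, list(), seed = 2)$true_class, "low")
  s_myo <- compose_segment(clean,
                           list(noise_event("myoelectric", 0.5, 3.5, 0.4)),
                           seed = 2)
  expect_identical(s_myo$true_class, "mild_myo")
  s_mot <- compose_segment(clean,
                           list(noise_event("motion", 1.0, 3.5, 0.8)),
                           seed = 2)
  expect_identical(s_mot$true_class, "severe_motion")
})

test_that("composed noise respects the peak-ratio amplitude contract", {
  for (ratio in c(0.25, 0.5, 0.85)) {
    for (amp in c(0.6, 1.5)) {
      clean <- generate_clean_segment(clean_ecg_params(r_amplitude_mv = amp),
                                      seed = 4)
      ev <- noise_event("myoelectric", 0.4, 3.2, ratio)
      noisy <- compose_segment(clean, list(ev), seed = 9)
      added <- noisy$samples - clean$samples
      expect_equal(max(abs(added)) / amp, ratio, tolerance = 0.01)
    }
  }
})

test_that("overlapping events are rejected", {
  clean <- generate_clean_segment(clean_ecg_params(), seed = 1)
  ev <- list(noise_event("motion", 0.5, 2.0, 0.3),
             noise_event("myoelectric", 1.5, 3.5, 0.3))
  expect_error(compose_segment(clean, ev, seed = 1), "overlap")
})

test_that("dataset generation delivers exact counts, reproducibly", {
  spec <- dataset_spec(counts = tiny_counts(10), seed = 7)
  ds <- generate_dataset(spec)
  expect_length(ds$segments, 50)
  expect_identical(as.integer(table(factor(ds$labels, quality_classes()))),
                   rep(10L, 5))
  ds2 <- generate_dataset(spec)
  expect_identical(segment_matrix(ds), segment_matrix(ds2))
  empty <- generate_dataset(dataset_spec(counts = tiny_counts(0)))
  expect_length(empty$segments, 0)
})

test_that("dataset spec validates severity ranges", {
  expect_error(dataset_spec(mild_ratio_range = c(0.2, 0.6)), "0.5")
  expect_error(dataset_spec(severe_ratio_range = c(0.3, 0.9)), "0.5")
  expect_error(dataset_spec(duration_range = c(1.5, 3)), "duration")
  expect_error(dataset_spec(counts = c(low = -1)), ">= 0")
})

test_that("generated labels round-trip through label_segment", {
  ds <- tiny_dataset(n = 20L, seed = 31L)
  relabelled <- vapply(ds$segments, function(s) {
    label_segment(s$events, s$r_height_mv)
  }, character(1))
  expect_identical(relabelled, ds$labels)
})
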