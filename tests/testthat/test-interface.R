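# Dataset containers, pipeline entry points, manifests, CLI.

test_that("text dataset export round-trips samples and labels", {
  ds <- tiny_dataset(n = 3L, seed = 51L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_text(ds, path)
  back <- read_dataset_text(path)
  expect_identical(back$labels, ds$labels)
  expect_equal(segment_matrix(back), segment_matrix(ds), tolerance = 1e-8)
})

test_that("binary container round-trips samples, labels and events", {
  skip_if_not_installed("arrow")
  ds <- tiny_dataset(n = 3L, seed = 52L)
  dir <- file.path(withr::local_tempdir(), "container")
  write_dataset_container(ds, dir)
  back <- read_dataset_container(dir)
  expect_identical(back$labels, ds$labels)
  expect_equal(segment_matrix(back), segment_matrix(ds), tolerance = 1e-12)
  i <- which(ds$labels == "severe_motion")[1]
  expect_identical(length(back$segments[[i]]$events),
                   length(ds$segments[[i]]$events))
  expect_equal(back$segments[[i]]$events[[1]]$peak_ratio,
               ds$segments[[i]]$events[[1]]$peak_ratio)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_segments, 15)
})

test_that("run_simulate writes a dataset plus manifest, deterministically", {
  dir1 <- file.path(withr::local_tempdir(), "sim1")
  dir2 <- file.path(withr::local_tempdir(), "sim2")
  config <- list(out_dir = dir1, seed = 9,
                 counts = c(low = 4, mild_myo = 2, severe_myo = 2,
                            mild_motion = 2, severe_motion = 2))
  run_simulate(config)
  man <- jsonlite::read_json(file.path(dir1, "run_manifest.json"))
  expect_equal(man$n_segments, 12)
  expect_equal(man$class_counts$low, 4)
  expect_equal(man$seed, 9)
  config$out_dir <- dir2
  run_simulate(config)
  expect_identical(readLines(file.path(dir1, "dataset.csv")),
                   readLines(file.path(dir2, "dataset.csv")))
})

test_that("run_simulate rejects invalid class counts", {
  config <- list(out_dir = file.path(withr::local_tempdir(), "bad"),
                 counts = c(low = -1))
  expect_error(run_simulate(config), ">= 0")
})

test_that("run_train then run_predict produce per-segment classes and levels", {
  work <- withr::local_tempdir()
  sim_dir <- file.path(work, "sim")
  run_simulate(list(out_dir = sim_dir, seed = 3,
                    counts = c(low = 8, mild_myo = 4, severe_myo = 4,
                               mild_motion = 4, severe_motion = 4)))
  model_dir <- file.path(work, "model")
  run_train(list(dataset = sim_dir, out_dir = model_dir, seed = 2,
                 epochs = 1, batch_size = 24))
  for (nm in c("type", "motion_level", "myo_level")) {
    expect_true(file.exists(file.path(model_dir,
                                      paste0("subnetwork_", nm, ".rds"))))
    expect_true(file.exists(file.path(model_dir,
                                      paste0("history_", nm, ".csv"))))
  }
  # predict on a single 512-sample text segment
  seg <- generate_clean_segment(clean_ecg_params(), seed = 77)
  seg_path <- file.path(work, "segment.txt")
  write_ecg_text(seg$samples, seg_path, fs = 128)
  out_dir <- file.path(work, "pred")
  preds <- run_predict(list(model_dir = model_dir, input = seg_path,
                            out_dir = out_dir))
  expect_identical(nrow(preds), 1L)
  expect_true(preds$class %in% quality_classes())
  expect_identical(preds$level, class_to_level(preds$class))
  man <- jsonlite::read_json(file.path(out_dir, "run_manifest.json"))
  expect_true(man$aggregated_level %in% quality_levels())
  expect_true(file.exists(file.path(out_dir, "predictions.csv")))
})

test_that("run_predict segments a long record into floor(n/512) windows", {
  work <- withr::local_tempdir()
  sim_dir <- file.path(work, "sim")
  run_simulate(list(out_dir = sim_dir, seed = 5,
                    counts = c(low = 8, mild_myo = 4, severe_myo = 4,
                               mild_motion = 4, severe_motion = 4)))
  model_dir <- file.path(work, "model")
  run_train(list(dataset = sim_dir, out_dir = model_dir, seed = 2,
                 epochs = 1, batch_size = 24))
  # one minute at 128 Hz -> 15 four-second segments
  rec <- rep(generate_clean_segment(clean_ecg_params(), seed = 1)$samples, 15)
  rec_path <- file.path(work, "record.txt")
  write_ecg_text(rec, rec_path, fs = 128)
  preds <- run_predict(list(model_dir = model_dir, input = rec_path,
                            out_dir = file.path(work, "pred")))
  expect_identical(nrow(preds), 15L)
  # an input shorter than one window warns and yields no predictions
  short_path <- file.path(work, "short.txt")
  write_ecg_text(rnorm(100), short_path, fs = 128)
  expect_warning(
    p0 <- run_predict(list(model_dir = model_dir, input = short_path,
                           out_dir = file.path(work, "pred0"))),
    "shorter")
  expect_identical(nrow(p0), 0L)
})

test_that("missing configuration fields give clear errors", {
  expect_error(run_train(list(out_dir = "x")), "dataset")
  expect_error(run_predict(list(input = "x", out_dir = "y")), "model_dir")
  expect_error(run_simulate(list()), "out_dir")
})

test_that("the command-line tool simulates with exit code 0 and rejects bad input", {
  cli <- system.file("cli", "ecgsqc", package = "ecgsqc")
  skip_if(cli == "", "CLI script not installed")
  work <- withr::local_tempdir()
  cfg_path <- file.path(work, "config.json")
  jsonlite::write_json(list(out_dir = file.path(work, "out"), seed = 2,
                            counts = list(low = 2, mild_myo = 1,
                                          severe_myo = 1, mild_motion = 1,
                                          severe_motion = 1)),
                       cfg_path, auto_unbox = TRUE)
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2(rscript, c(cli, "simulate", "--config", cfg_path),
                    env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(work, "out", "run_manifest.json")))
  # user error: missing config file
  bad <- suppressWarnings(
    system2(rscript, c(cli, "simulate", "--config", "/nonexistent.json"),
            env = env, stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 1L)
})
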