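# Cascade routing and evaluation metrics (one-vs-rest Se/Sp, overall Ac,
# per-record accuracy).

test_that("stubbed stage probabilities route to the documented classes", {
  expect_identical(cascade_route(c(0.1, 0.8, 0.1), motion = c(0.3, 0.7)),
                   "severe_motion")
  expect_identical(cascade_route(c(0.9, 0.05, 0.05)), "low")
  expect_identical(cascade_route(c(0.1, 0.2, 0.7), myo = c(0.8, 0.2)),
                   "mild_myo")
  # ties break to the lowest class index
  expect_identical(cascade_route(c(1, 1, 1) / 3, motion = c(0.5, 0.5),
                                 myo = c(0.5, 0.5)), "low")
  expect_identical(cascade_route(c(0.1, 0.45, 0.45), motion = c(0.5, 0.5)),
                   "mild_motion")
  # batch form with row-aligned stage-2 matrices
  s1 <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  s2 <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  out <- cascade_route(s1, motion = s2, myo = s2)
  expect_identical(out, c("low", "severe_motion", "mild_myo"))
  # routed level always equals class_to_level of the prediction
  expect_identical(class_to_level(out), c("low", "severe", "mild"))
})

test_that("missing stage-2 probabilities are a configuration error", {
  expect_error(cascade_route(c(0.1, 0.8, 0.1)), "motion")
  expect_error(cascade_route(c(0.1, 0.1, 0.8)), "myo")
})

test_that("cascade_predict validates its subnetworks", {
  sn <- build_subnetwork(subnetwork_spec(n_blocks = c(1L, 1L, 1L),
                                         channels = c(2L, 2L, 4L)), seed = 1)
  expect_error(cascade_predict(matrix(0, 1, 512), sn, sn, sn), "trained")
})

test_that("Se, Sp and Ac reproduce hand-computed values", {
  cm <- matrix(c(9, 2, 1, 8), 2, byrow = FALSE,
               dimnames = list(c("a", "b"), c("a", "b")))
  # row a: 9 correct, 1 wrong -> TP = 9, FN = 1, FP = 2, TN = 8
  expect_equal(sensitivity(cm, "a"), 0.9)
  expect_equal(specificity(cm, "a"), 0.8)
  expect_equal(overall_accuracy(cm), 0.85)
})

test_that("metrics match brute-force one-vs-rest on enumerated matrices", {
  brute <- function(cm, k) {
    truth <- rep(seq_len(nrow(cm)), times = rowSums(cm))
    pred <- unlist(lapply(seq_len(nrow(cm)), function(i) {
      rep(seq_len(ncol(cm)), times = cm[i, ])
    }))
    tp <- sum(truth == k & pred == k)
    fn <- sum(truth == k & pred != k)
    fp <- sum(truth != k & pred == k)
    tn <- sum(truth != k & pred != k)
    list(se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         sp = if (fp + tn > 0) tn / (fp + tn) else NA_real_)
  }
  set.seed(21)
  for (trial in 1:25) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, 3), k,
                 dimnames = list(letters[1:k], letters[1:k]))
    for (cls in seq_len(k)) {
      ref <- brute(cm, cls)
      expect_equal(sensitivity(cm, cls), ref$se)
      expect_equal(specificity(cm, cls), ref$sp)
    }
    expect_equal(overall_accuracy(cm), sum(diag(cm)) / sum(cm))
    # structural identities
    expect_equal(sum(diag(cm)),
                 sum(vapply(seq_len(k), function(i) cm[i, i], numeric(1))))
    for (cls in seq_len(k)) {
      v <- ecgsqc:::.ovr_counts(cm, cls)
      expect_equal(unname(v["tp"] + v["fn"]), sum(cm[cls, ]))
      expect_equal(unname(v["tp"] + v["fp"]), sum(cm[, cls]))
    }
  }
})

test_that("degenerate metrics report NA, and identity matrices are perfect", {
  id <- diag(3)
  dimnames(id) <- list(1:3, 1:3)
  for (cls in 1:3) {
    expect_equal(sensitivity(id, cls), 1)
    expect_equal(specificity(id, cls), 1)
  }
  expect_equal(overall_accuracy(id), 1)
  # all predictions in one column: other classes' Se undefined-free but that
  # column's Sp = 0
  cm <- matrix(c(5, 7, 0, 0), 2, dimnames = list(1:2, 1:2))
  expect_equal(specificity(cm, 1), 0)
  # a class never present in truth has undefined sensitivity
  cm2 <- matrix(c(3, 1, 0, 0), 2, byrow = TRUE, dimnames = list(1:2, 1:2))
  expect_true(is.na(sensitivity(cm2, 2)))
})

test_that("confusion_matrix orders quality classes canonically", {
  truth <- c("low", "severe_myo", "mild_motion", "low")
  pred <- c("low", "mild_myo", "mild_motion", "severe_motion")
  cm <- confusion_matrix(truth, pred, classes = quality_classes())
  expect_identical(rownames(cm), quality_classes())
  expect_identical(sum(cm), 4L)
  expect_identical(cm["low", "severe_motion"], 1L)
})

test_that("per-record accuracy matches pooled accuracy when size-weighted", {
  set.seed(31)
  truth <- sample(quality_classes(), 60, TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(quality_classes(), 60, TRUE))
  rec <- rep(c("100", "101", "102"), each = 20)
  tab <- per_record_accuracy(truth, pred, rec)
  expect_identical(tab$record, c("100", "101", "102"))
  pooled <- mean(truth == pred)
  expect_equal(sum(tab$n * tab$accuracy) / sum(tab$n), pooled)
  # single record equals the overall accuracy
  one <- per_record_accuracy(truth, pred, rep("x", 60))
  expect_equal(one$accuracy, pooled)
  # explicit small case
  tab2 <- per_record_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "a"),
                              c(1, 1, 2, 2))
  expect_equal(tab2$accuracy, c(1.0, 0.5))
})

test_that("eval_report assembles metrics and exports them", {
  truth <- c("low", "low", "mild_myo", "severe_myo", "mild_motion")
  pred <- c("low", "mild_myo", "mild_myo", "severe_myo", "mild_motion")
  rep_ <- eval_report(truth, pred, record = c(1, 1, 1, 2, 2))
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$overall_accuracy, 0.8)
  expect_identical(nrow(rep_$per_class), length(unique(c(truth, pred))))
  dir <- withr::local_tempdir()
  write_eval_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "confusion.tsv")))
  got <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(got$overall_accuracy, 0.8)
})
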