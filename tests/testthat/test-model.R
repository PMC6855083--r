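# Network construction: published parameter counts, feature shapes,
# softmax/loss behaviour, seeded initialization, gradient correctness.

test_that("baseline and cascade match the published parameter counts", {
  baseline <- build_baseline(baseline_spec(), seed = 1)
  expect_equal(round(count_trainable_parameters(baseline) / 1e6, 2), 0.28)
  s1 <- build_subnetwork(subnetwork_spec(n_classes = 3L), seed = 1)
  s2 <- build_subnetwork(subnetwork_spec(n_classes = 2L), seed = 2)
  s3 <- build_subnetwork(subnetwork_spec(n_classes = 2L), seed = 3)
  total <- count_trainable_parameters(s1) + count_trainable_parameters(s2) +
    count_trainable_parameters(s3)
  expect_equal(round(total / 1e6, 1), 3.2)
})

test_that("parameter counts agree with closed-form layer arithmetic", {
  grid <- list(
    list(n_blocks = c(1L, 2L, 5L), channels = c(32L, 64L, 128L)),
    list(n_blocks = c(1L, 1L, 1L), channels = c(32L, 64L, 128L)),
    list(n_blocks = c(2L, 2L, 2L), channels = c(8L, 16L, 32L)),
    list(n_blocks = c(1L, 3L, 4L), channels = c(16L, 32L, 64L))
  )
  for (g in grid) {
    bl <- build_baseline(baseline_spec(g$n_blocks, g$channels), seed = 1)
    expect_equal(count_trainable_parameters(bl),
                 count_params_closed_form(g$n_blocks, g$channels,
                                          "baseline"))
    for (k in c(2L, 3L)) {
      sn <- build_subnetwork(subnetwork_spec(g$n_blocks, k, g$channels),
                             seed = 1)
      expect_equal(count_trainable_parameters(sn),
                   count_params_closed_form(g$n_blocks, g$channels,
                                            "subnetwork", k))
    }
  }
})

test_that("a lone dense layer (10 -> 5 with bias) contributes 55 parameters", {
  # difference between two subnetworks whose heads differ only in K
  s3 <- build_subnetwork(subnetwork_spec(n_classes = 3L), seed = 1)
  s2 <- build_subnetwork(subnetwork_spec(n_classes = 2L), seed = 1)
  expect_identical(count_trainable_parameters(s3) -
                     count_trainable_parameters(s2), 128L + 1L)
  # and directly via the closed form for a dense layer
  dense_params <- function(n_in, n_out) n_in * n_out + n_out
  expect_identical(dense_params(10, 5), 55)
})

test_that("feature dimensions propagate as 384 + 256 = 640 (baseline 256)", {
  sn <- build_subnetwork(subnetwork_spec(), seed = 1)
  expect_identical(sn$arch$fc_in, 640L)
  # shape oracle: 257->64->16->4, 63->31->15->3, so 4*3*32 = 384; CNN2
  # 512->128->32->8, so 8*32 = 256
  expect_identical(c(257L %/% 4L %/% 4L %/% 4L, 63L %/% 2L %/% 2L %/% 4L),
                   c(4L, 3L))
  bl <- build_baseline(baseline_spec(), seed = 1)
  expect_identical(bl$arch$fc_in, 256L)
})

test_that("forward pass returns normalized probabilities, deterministically", {
  sn <- build_subnetwork(subnetwork_spec(), seed = 4)
  set.seed(10)
  seg <- matrix(rnorm(2 * 512), 2)
  prep <- prepare_inputs(seg)
  p <- network_forward(sn, prep$spec, prep$raw)
  expect_identical(dim(p), c(2L, 3L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # evaluation mode is deterministic
  expect_identical(p, network_forward(sn, prep$spec, prep$raw))
})

test_that("network construction is seed-deterministic", {
  a <- build_subnetwork(subnetwork_spec(), seed = 9)
  b <- build_subnetwork(subnetwork_spec(), seed = 9)
  expect_identical(a$par, b$par)
  c <- build_subnetwork(subnetwork_spec(), seed = 10)
  expect_false(identical(a$par, c$par))
  expect_identical(build_baseline(seed = 3)$par, build_baseline(seed = 3)$par)
})

test_that("dropout is active only in training mode", {
  sn <- build_subnetwork(subnetwork_spec(), seed = 4)
  set.seed(11)
  prep <- prepare_inputs(matrix(rnorm(512), 1))
  inp <- list(as.numeric(prep$spec), as.numeric(t(prep$raw)))
  mask1 <- matrix((runif(128) >= 0.5) * 2, 128, 1)
  mask2 <- matrix((runif(128) >= 0.5) * 2, 128, 1)
  p1 <- ecgsqc:::.cnn_run_cpp(sn$arch, sn$par, inp, integer(0), sn$bn_state,
                              mask1, TRUE, FALSE, 0L, TRUE)$probs
  p2 <- ecgsqc:::.cnn_run_cpp(sn$arch, sn$par, inp, integer(0), sn$bn_state,
                              mask2, TRUE, FALSE, 0L, TRUE)$probs
  expect_false(identical(p1, p2))
})

test_that("cross-entropy loss reproduces hand-computed values", {
  # perfect one-hot prediction
  expect_lt(cross_entropy_loss(c(1, 0, 0), c(1, 0, 0)), 1e-9)
  # uniform 3-class vs one-hot: -[log(1/3) + 2 log(2/3)]
  expect_equal(cross_entropy_loss(rep(1 / 3, 3), c(1, 0, 0)),
               -(log(1 / 3) + 2 * log(2 / 3)), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(rep(1 / 3, 3), c(1, 0, 0)), 1.9095,
               tolerance = 1e-4)
  # categorical variant drops the (1 - y) terms
  expect_equal(cross_entropy_loss(rep(1 / 3, 3), c(1, 0, 0), "categorical"),
               log(3), tolerance = 1e-12)
  # symmetry under simultaneous permutation
  perm <- c(2, 3, 1)
  p <- c(0.2, 0.5, 0.3); y <- c(0, 1, 0)
  expect_equal(cross_entropy_loss(p, y),
               cross_entropy_loss(p[perm], y[perm]), tolerance = 1e-12)
  expect_error(cross_entropy_loss(c(0.5, 0.5), c(1, 0, 0)), "shape")
})

test_that("engine loss matches the R-level loss on the same probabilities", {
  sn <- build_subnetwork(subnetwork_spec(n_blocks = c(1L, 1L, 1L),
                                         channels = c(4L, 4L, 8L)), seed = 2)
  set.seed(12)
  prep <- prepare_inputs(matrix(rnorm(3 * 512), 3))
  inp <- list(as.numeric(prep$spec), as.numeric(t(prep$raw)))
  y <- c(0L, 2L, 1L)
  res <- ecgsqc:::.cnn_run_cpp(sn$arch, sn$par, inp, y, sn$bn_state, NULL,
                               TRUE, FALSE, 0L, FALSE)
  onehot <- diag(3)[y + 1L, ]
  expect_equal(res$loss, cross_entropy_loss(t(res$probs), onehot),
               tolerance = 1e-9)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- subnetwork_spec(n_blocks = c(1L, 1L, 1L), n_classes = 3L,
                          channels = c(2L, 3L, 4L))
  net <- build_subnetwork(spec, seed = 42)
  set.seed(7)
  m <- 3
  inp <- list(as.numeric(array(rnorm(257 * 63 * m), c(257, 63, m))),
              as.numeric(t(matrix(rnorm(m * 512), m))))
  y <- c(0L, 1L, 2L)
  run <- function(par, grad = FALSE) {
    ecgsqc:::.cnn_run_cpp(net$arch, par, inp, y, net$bn_state, NULL,
                          TRUE, grad, 0L, FALSE)
  }
  r0 <- run(net$par, TRUE)
  set.seed(1)
  idx <- sample(length(net$par), 80)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    p <- net$par
    p[i] <- p[i] + eps; lp <- run(p)$loss
    p[i] <- p[i] - 2 * eps; lm <- run(p)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  ana <- r0$grad[idx]
  rel <- abs(num - ana) / pmax(abs(num) + abs(ana), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("checkpoints round-trip with an architecture hash", {
  net <- build_subnetwork(subnetwork_spec(n_blocks = c(1L, 1L, 1L),
                                          channels = c(2L, 2L, 4L)), seed = 5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ckpt")
  save_network(net, path)
  back <- load_network(path)
  expect_identical(back$par, net$par)
  expect_identical(back$arch, net$arch)
  # tampering with the sidecar hash is detected
  side <- jsonlite::read_json(paste0(path, ".json"))
  side$arch_hash <- "00000000"
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_network(path), "hash")
})

test_that("invalid specs are rejected", {
  expect_error(subnetwork_spec(n_classes = 5L), "2 or 3")
  expect_error(subnetwork_spec(n_blocks = c(0L, 1L, 1L)))
  expect_error(build_subnetwork(baseline_spec()), "subnetwork_spec")
  expect_error(build_baseline(subnetwork_spec()), "baseline_spec")
})
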