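# Network construction: the baseline five-class CNN on the raw 1 x 512
# signal, and the cascade subnetworks that fuse a spectrogram branch (CNN1,
# 3 x 3 "block1" convolutions) with a raw-signal branch (CNN2, 1 x 3
# "block2" convolutions) into a 128-unit fully connected head.
#
# Conventions pinned here (they reproduce the published 0.28M / 3.2M
# trainable-parameter counts): size-preserving convolution padding, stride
# 1, non-overlapping max-pooling with floor division on odd extents,
# convolution biases kept alongside batch normalization, and a bare 1 x 1
# convolution + ReLU tail (no batch norm) reducing to 32 feature maps.

#' Specify a cascade subnetwork
#'
#' Each subnetwork fuses two convolutional feature extractors: CNN1 consumes
#' the 257 x 63 spectrogram through three stages of 3 x 3
#' convolution/batch-norm/ReLU blocks (block counts `n_blocks`, channels
#' `channels`, max-pools 4x2, 4x2, 4x4), and CNN2 consumes the 1 x 512
#' z-scored signal through 1 x 3 blocks with 1x4 pools.  Both end in a
#' 1 x 1 convolution to 32 maps; the flattened features (384 + 256 = 640
#' with defaults) feed a 128-unit fully connected layer with dropout 0.5 and
#' a softmax over `n_classes`.
#'
#' @param n_blocks Integer triple: blocks per stage (default `c(1, 2, 5)`).
#' @param n_classes 3 (interference type: low / motion / myoelectric) or 2
#'   (interference level: mild / severe).
#' @param channels Integer triple of stage widths (default `c(32, 64, 128)`).
#' @param dropout_p Dropout probability on the 128-unit layer (default 0.5).
#' @return A `subnetwork_spec` object.
#' @export
subnetwork_spec <- function(n_blocks = c(1L, 2L, 5L), n_classes = 3L,
                            channels = c(32L, 64L, 128L), dropout_p = 0.5) {
  stopifnot(length(n_blocks) == 3L, all(n_blocks >= 1L),
            length(channels) == 3L, all(channels >= 1L))
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  structure(list(n_blocks = as.integer(n_blocks),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(channels),
                 dropout_p = dropout_p),
            class = "subnetwork_spec")
}

#' Specify the baseline five-class network
#'
#' A single CNN on the raw 1 x 512 signal: three stages of 1 x 3
#' convolution blocks with counts `n_blocks` (default `c(1, 2, 5)`) and
#' channels `channels`, each followed by a 1x4 max-pool, then a 1 x 1
#' convolution to 32 maps, a 128-unit fully connected layer (no dropout)
#' and a softmax over the five quality classes.
#'
#' @inheritParams subnetwork_spec
#' @return A `baseline_spec` object.
#' @export
baseline_spec <- function(n_blocks = c(1L, 2L, 5L),
                          channels = c(32L, 64L, 128L)) {
  stopifnot(length(n_blocks) == 3L, all(n_blocks >= 1L),
            length(channels) == 3L, all(channels >= 1L))
  structure(list(n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels),
                 n_classes = 5L),
            class = "baseline_spec")
}

# op-row helpers for the engine spec matrix: (code, a, b, c, d)
.op_conv <- function(kh, kw, cin, cout) c(1L, kh, kw, cin, cout)
.op_bn <- function(ch) c(2L, ch, 0L, 0L, 0L)
.op_relu <- function() c(3L, 0L, 0L, 0L, 0L)
.op_pool <- function(ph, pw) c(4L, ph, pw, 0L, 0L)

# build the op matrix for one convolutional branch
.branch_ops <- function(kernel, n_blocks, channels, pools, cin = 1L,
                        tail_maps = 32L) {
  ops <- list()
  cur <- cin
  for (s in 1:3) {
    for (b in seq_len(n_blocks[s])) {
      ops <- c(ops, list(.op_conv(kernel[1], kernel[2], cur, channels[s]),
                         .op_bn(channels[s]), .op_relu()))
      cur <- channels[s]
    }
    ops <- c(ops, list(.op_pool(pools[[s]][1], pools[[s]][2])))
  }
  ops <- c(ops, list(.op_conv(1L, 1L, cur, tail_maps), .op_relu()))
  do.call(rbind, ops)
}

# spatial size after a branch (floor pooling)
.branch_out_dims <- function(h, w, ops) {
  for (i in seq_len(nrow(ops))) {
    if (ops[i, 1] == 4L) {
      h <- h %/% ops[i, 2]
      w <- w %/% ops[i, 3]
    }
  }
  c(h, w)
}

.build_arch <- function(spec) {
  if (inherits(spec, "subnetwork_spec")) {
    b1 <- list(h = 257L, w = 63L, cin = 1L,
               ops = .branch_ops(c(3L, 3L), spec$n_blocks, spec$channels,
                                 list(c(4L, 2L), c(4L, 2L), c(4L, 4L))))
    b2 <- list(h = 1L, w = 512L, cin = 1L,
               ops = .branch_ops(c(1L, 3L), spec$n_blocks, spec$channels,
                                 list(c(1L, 4L), c(1L, 4L), c(1L, 4L))))
    d1 <- .branch_out_dims(257L, 63L, b1$ops)
    d2 <- .branch_out_dims(1L, 512L, b2$ops)
    fc_in <- 32L * prod(d1) + 32L * prod(d2)
    list(branches = list(b1, b2), fc_in = as.integer(fc_in),
         fc_hidden = 128L, n_classes = spec$n_classes,
         dropout_p = spec$dropout_p)
  } else if (inherits(spec, "baseline_spec")) {
    b <- list(h = 1L, w = 512L, cin = 1L,
              ops = .branch_ops(c(1L, 3L), spec$n_blocks, spec$channels,
                                list(c(1L, 4L), c(1L, 4L), c(1L, 4L))))
    d <- .branch_out_dims(1L, 512L, b$ops)
    list(branches = list(b), fc_in = as.integer(32L * prod(d)),
         fc_hidden = 128L, n_classes = 5L, dropout_p = 0)
  } else {
    stop("spec must be a subnetwork_spec or baseline_spec")
  }
}

# He-normal initialization of all parameter tensors, in engine traversal
# order; returns list(par, par_shapes, bn_state)
.init_params <- function(arch, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  par <- list()
  shapes <- list()
  n_bn <- 0L
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  for (br in arch$branches) {
    ops <- br$ops
    for (i in seq_len(nrow(ops))) {
      code <- ops[i, 1]
      if (code == 1L) { # conv: W (cin*kh*kw x cout), b (cout)
        kh <- ops[i, 2]; kw <- ops[i, 3]; cin <- ops[i, 4]; cout <- ops[i, 5]
        fan_in <- cin * kh * kw
        par <- c(par, list(he(fan_in, fan_in * cout), numeric(cout)))
        shapes <- c(shapes, list(c(fan_in, cout), cout))
      } else if (code == 2L) { # BN: gamma = 1, beta = 0
        ch <- ops[i, 2]
        par <- c(par, list(rep(1, ch), numeric(ch)))
        shapes <- c(shapes, list(ch, ch))
        n_bn <- n_bn + ch
      }
    }
  }
  par <- c(par, list(he(arch$fc_in, arch$fc_in * arch$fc_hidden),
                     numeric(arch$fc_hidden),
                     he(arch$fc_hidden, arch$fc_hidden * arch$n_classes),
                     numeric(arch$n_classes)))
  shapes <- c(shapes, list(c(arch$fc_in, arch$fc_hidden), arch$fc_hidden,
                           c(arch$fc_hidden, arch$n_classes), arch$n_classes))
  # running BN state: mean 0, var 1, packed (mean, var) per BN layer
  bn_state <- numeric(0)
  for (br in arch$branches) {
    ops <- br$ops
    for (i in seq_len(nrow(ops))) {
      if (ops[i, 1] == 2L) {
        ch <- ops[i, 2]
        bn_state <- c(bn_state, numeric(ch), rep(1, ch))
      }
    }
  }
  list(par = unlist(par), shapes = shapes, bn_state = bn_state)
}

.new_network <- function(spec, seed, kind) {
  arch <- .build_arch(spec)
  ini <- .init_params(arch, seed)
  structure(list(kind = kind, spec = spec, arch = arch,
                 par = ini$par, bn_state = ini$bn_state,
                 seed = as.integer(seed), trained = FALSE,
                 loss_type = "bernoulli_sum"),
            class = "ecg_network")
}

#' Build an untrained cascade subnetwork
#'
#' @param spec A [subnetwork_spec()].
#' @param seed Integer seed for He-normal weight initialization.
#' @return An `ecg_network` object holding the architecture, the flat
#'   parameter vector and the batch-norm running statistics.
#' @export
#' @examples
#' net <- build_subnetwork(subnetwork_spec(), seed = 1)
#' count_trainable_parameters(net)
build_subnetwork <- function(spec = subnetwork_spec(), seed = 1L) {
  if (!inherits(spec, "subnetwork_spec")) {
    stop("spec must be a subnetwork_spec")
  }
  .new_network(spec, seed, "subnetwork")
}

#' Build the untrained baseline network
#'
#' @param spec A [baseline_spec()].
#' @param seed Integer seed for He-normal weight initialization.
#' @return An `ecg_network` object.
#' @export
build_baseline <- function(spec = baseline_spec(), seed = 1L) {
  if (!inherits(spec, "baseline_spec")) stop("spec must be a baseline_spec")
  .new_network(spec, seed, "baseline")
}

#' Count trainable parameters of a network
#'
#' Sums the element counts of every trainable tensor: convolution kernels
#' and biases, batch-norm scales and shifts, fully connected weights and
#' biases.  Batch-norm running statistics are not trainable and are not
#' counted.
#'
#' @param network An `ecg_network` (or an `ecg_cascade` fit, in which case
#'   the three subnetworks are summed).
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(network) {
  if (inherits(network, "ecg_cascade")) {
    return(sum(vapply(network$subnetworks, count_trainable_parameters,
                      numeric(1))))
  }
  if (!inherits(network, "ecg_network")) {
    stop("network must be an ecg_network or ecg_cascade")
  }
  length(network$par)
}

# assemble engine inputs from prepared tensors (branch data ordered with
# the per-sample frame fastest, samples consecutive)
.engine_inputs <- function(net, spec_arr, raw_mat) {
  if (net$kind == "subnetwork") {
    list(as.numeric(spec_arr), as.numeric(t(raw_mat)))
  } else {
    list(as.numeric(t(raw_mat)))
  }
}

#' Forward pass of a network
#'
#' Evaluation-mode forward pass (dropout disabled, batch-norm running
#' statistics): deterministic for fixed weights.
#'
#' @param network An `ecg_network`.
#' @param spec_arr Standardized spectrogram array 257 x 63 x n (ignored for
#'   baseline networks).
#' @param raw_mat Matrix n x 512 of z-scored signals.
#' @param precision `"single"` or `"double"` arithmetic.
#' @return Matrix n x K of class probabilities (rows sum to 1).
#' @export
network_forward <- function(network, spec_arr = NULL, raw_mat,
                            precision = c("single", "double")) {
  precision <- match.arg(precision)
  if (is.vector(raw_mat)) raw_mat <- matrix(raw_mat, nrow = 1)
  if (network$kind == "subnetwork" && is.null(spec_arr)) {
    stop("subnetworks require the spectrogram input")
  }
  res <- .cnn_run_cpp(network$arch, network$par,
                      .engine_inputs(network, spec_arr, raw_mat),
                      integer(0), network$bn_state, NULL,
                      FALSE, FALSE, 0L, precision == "single")
  t(res$probs)
}

#' Cross-entropy loss over softmax outputs
#'
#' The default `"bernoulli_sum"` form sums a Bernoulli cross-entropy term
#' over every output unit,
#' `-sum_j [ y_j log O_j + (1 - y_j) log(1 - O_j) ]`, applied to the
#' softmax outputs; `"categorical"` is the conventional
#' `-sum_j y_j log O_j`.  Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before the logarithms.
#'
#' @param predicted Numeric vector of K predicted probabilities (or a
#'   matrix, one distribution per row).
#' @param target One-hot numeric vector (or matrix) of the same shape.
#' @param form `"bernoulli_sum"` (default) or `"categorical"`.
#' @return Mean loss over the rows (a single non-negative number).
#' @export
#' @examples
#' cross_entropy_loss(c(1/3, 1/3, 1/3), c(1, 0, 0))
cross_entropy_loss <- function(predicted, target,
                               form = c("bernoulli_sum", "categorical")) {
  form <- match.arg(form)
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  if (!all(dim(predicted) == dim(target))) {
    stop("predicted and target must have the same shape")
  }
  p <- pmin(pmax(predicted, 1e-12), 1 - 1e-12)
  if (form == "bernoulli_sum") {
    mean(rowSums(-(target * log(p) + (1 - target) * log(1 - p))))
  } else {
    mean(rowSums(-target * log(p)))
  }
}

#' @export
print.ecg_network <- function(x, ...) {
  cat(sprintf("ecg_network (%s): %s classes, %s parameters%s\n",
              x$kind, x$arch$n_classes,
              format(length(x$par), big.mark = ","),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# FNV-1a hash of a serialized object (architecture fingerprints)
.spec_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save / load a network checkpoint
#'
#' The weights go to a binary container (`<path>.rds`) and the architecture
#' to a JSON sidecar (`<path>.json`) carrying a hash of the architecture;
#' loading validates the hash.
#'
#' @param network An `ecg_network`.
#' @param path Checkpoint path without extension.
#' @return `save_network()`: invisibly, `path`; `load_network()`: the
#'   network.
#' @export
save_network <- function(network, path) {
  if (!inherits(network, "ecg_network")) stop("network must be an ecg_network")
  sidecar <- list(kind = network$kind,
                  n_classes = network$arch$n_classes,
                  fc_in = network$arch$fc_in,
                  n_parameters = length(network$par),
                  trained = network$trained,
                  arch_hash = .spec_hash(network$arch))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  saveRDS(network, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(paste0(path, ".rds"))
  side <- jsonlite::read_json(paste0(path, ".json"))
  if (!identical(side$arch_hash, .spec_hash(net$arch))) {
    stop("architecture hash mismatch between checkpoint and sidecar")
  }
  net
}
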