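#' Specification of a baseline model family
#'
#' Compact reference versions of the four comparison families. The exact
#' layer inventories are this package's own choices (documented below);
#' only ResNet-34 follows a fixed published topology (basic residual
#' blocks in stages of 3, 4, 6 and 3, single-channel input, 2-class head).
#'
#' * `cnn` - two stride-2 1-D convolutions over time (feature coefficients
#'   as channels) with ReLU, mean-pooled, linear head.
#' * `lstm` - one LSTM over the feature frames; last hidden state, linear
#'   head.
#' * `cnn_lstm` - one stride-2 1-D convolution + ReLU feeding an LSTM;
#'   last hidden state, linear head.
#' * `resnet34` - standard 34-layer residual network on the `tl x n_coeffs`
#'   feature matrix treated as a one-channel image; `base_width` scales all
#'   channel counts (64 reproduces the published widths).
#'
#' @param family One of `"cnn"`, `"lstm"`, `"cnn_lstm"`, `"resnet34"`.
#' @param input_shape Integer pair `(tl, n_coeffs)`.
#' @param width Channel / hidden width of the compact families.
#' @param base_width Stage-1 width of ResNet-34.
#' @return A `bs_baseline_spec` list.
#' @export
baseline_spec <- function(family = c("cnn", "lstm", "cnn_lstm", "resnet34"),
                          input_shape = c(164, 40), width = 32,
                          base_width = 64) {
  family <- match.arg(family)
  structure(
    list(family = family, input_shape = as.integer(input_shape),
         width = width, base_width = base_width),
    class = "bs_baseline_spec"
  )
}

#' Build a baseline model
#'
#' Returns a trainable model mapping a `tl x n_coeffs` feature matrix to
#' two class probabilities, behind the same interface as the Branchformer.
#'
#' @param spec A [baseline_spec()].
#' @param seed Integer seed for parameter initialisation.
#' @return A `bs_model`.
#' @export
build_baseline <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "bs_baseline_spec"))
  withr::local_seed(seed)
  switch(spec$family,
    cnn      = build_cnn(spec),
    lstm     = build_lstm(spec),
    cnn_lstm = build_cnn_lstm(spec),
    resnet34 = build_resnet34(spec),
    stop("unknown baseline family: ", spec$family, call. = FALSE)
  )
}

#' Build any of the five model families by name
#'
#' Dispatcher used by the sweep runner: `"branchformer"` or one of the
#' four baseline families.
#'
#' @param family Model family name.
#' @param input_shape Integer pair `(tl, n_coeffs)`.
#' @param seed Integer seed.
#' @param encoder_cfg Optional [encoder_config()] for the Branchformer.
#' @param ... Passed to [baseline_spec()] for baselines.
#' @return A `bs_model`.
#' @export
build_model <- function(family, input_shape, seed = 1, encoder_cfg = NULL,
                        ...) {
  if (family == "branchformer") {
    cfg <- encoder_cfg %||% encoder_config()
    init_branchformer(input_shape[2], cfg, seed = seed)
  } else {
    build_baseline(baseline_spec(family, input_shape, ...), seed = seed)
  }
}

build_cnn <- function(spec) {
  Cin <- spec$input_shape[2]
  w <- spec$width
  params <- list(
    conv1.W = glorot(5 * Cin, w), conv1.b = rep(0, w),
    conv2.W = glorot(5 * w, 2 * w), conv2.b = rep(0, 2 * w),
    head.W = glorot(2 * w, 2), head.b = rep(0, 2)
  )
  fwd <- function(params, prep, cfg, training = FALSE, buffers = NULL) {
    h <- ag_relu(ag_conv1d(as_ag_x(prep), params[["conv1.W"]],
                           params[["conv1.b"]], 2L, prep$B, prep$T))
    T1 <- ceiling(prep$T / 2)
    h <- ag_relu(ag_conv1d(h, params[["conv2.W"]], params[["conv2.b"]],
                           2L, prep$B, T1))
    T2 <- ceiling(T1 / 2)
    pooled <- ag_mean_pool_time(h, prep$B, T2)
    ag_add_bias(ag_matmul(pooled, params[["head.W"]]), params[["head.b"]])
  }
  new_bs_model("cnn", params, spec, fwd, prepare_sequence)
}

lstm_init <- function(Fin, H) {
  lim <- sqrt(6 / (Fin + 4 * H))
  list(
    W = matrix(stats::runif(Fin * 4 * H, -lim, lim), Fin, 4 * H),
    U = matrix(stats::runif(H * 4 * H, -sqrt(6 / (5 * H)),
                            sqrt(6 / (5 * H))), H, 4 * H),
    b = c(rep(0, H), rep(1, H), rep(0, 2 * H))   # forget-gate bias 1
  )
}

build_lstm <- function(spec) {
  Cin <- spec$input_shape[2]
  w <- spec$width
  li <- lstm_init(Cin, w)
  params <- list(
    lstm.W = li$W, lstm.U = li$U, lstm.b = li$b,
    head.W = glorot(w, 2), head.b = rep(0, 2)
  )
  fwd <- function(params, prep, cfg, training = FALSE, buffers = NULL) {
    h <- ag_lstm(as_ag_x(prep), params[["lstm.W"]], params[["lstm.U"]],
                 params[["lstm.b"]], prep$B, prep$T, return_last = TRUE)
    ag_add_bias(ag_matmul(h, params[["head.W"]]), params[["head.b"]])
  }
  new_bs_model("lstm", params, spec, fwd, prepare_sequence)
}

build_cnn_lstm <- function(spec) {
  Cin <- spec$input_shape[2]
  w <- spec$width
  li <- lstm_init(w, w)
  params <- list(
    conv1.W = glorot(5 * Cin, w), conv1.b = rep(0, w),
    lstm.W = li$W, lstm.U = li$U, lstm.b = li$b,
    head.W = glorot(w, 2), head.b = rep(0, 2)
  )
  fwd <- function(params, prep, cfg, training = FALSE, buffers = NULL) {
    h <- ag_relu(ag_conv1d(as_ag_x(prep), params[["conv1.W"]],
                           params[["conv1.b"]], 2L, prep$B, prep$T))
    T1 <- ceiling(prep$T / 2)
    h <- ag_lstm(h, params[["lstm.W"]], params[["lstm.U"]],
                 params[["lstm.b"]], prep$B, T1, return_last = TRUE)
    ag_add_bias(ag_matmul(h, params[["head.W"]]), params[["head.b"]])
  }
  new_bs_model("cnn_lstm", params, spec, fwd, prepare_sequence)
}

#' Residual block counts per stage of ResNet-34
#' @return Integer vector `c(3, 4, 6, 3)`.
#' @export
resnet34_stage_blocks <- function() c(3L, 4L, 6L, 3L)

build_resnet34 <- function(spec) {
  bw <- spec$base_width
  widths <- bw * c(1, 2, 4, 8)
  blocks <- resnet34_stage_blocks()
  params <- list(
    stem.W = glorot(7 * 7 * 1, widths[1]), stem.b = rep(0, widths[1]),
    stem.bn.gamma = rep(1, widths[1]), stem.bn.beta = rep(0, widths[1])
  )
  c_in <- widths[1]
  for (s in seq_along(blocks)) {
    c_out <- widths[s]
    for (bl in seq_len(blocks[s])) {
      pre <- sprintf("s%d.b%d.", s, bl)
      stride1 <- if (bl == 1 && s > 1) 2L else 1L
      params[[paste0(pre, "conv1.W")]] <- glorot(9 * c_in, c_out)
      params[[paste0(pre, "conv1.b")]] <- rep(0, c_out)
      params[[paste0(pre, "bn1.gamma")]] <- rep(1, c_out)
      params[[paste0(pre, "bn1.beta")]] <- rep(0, c_out)
      params[[paste0(pre, "conv2.W")]] <- glorot(9 * c_out, c_out)
      params[[paste0(pre, "conv2.b")]] <- rep(0, c_out)
      params[[paste0(pre, "bn2.gamma")]] <- rep(1, c_out)
      params[[paste0(pre, "bn2.beta")]] <- rep(0, c_out)
      if (stride1 == 2L || c_in != c_out) {
        params[[paste0(pre, "down.W")]] <- glorot(1 * c_in, c_out)
        params[[paste0(pre, "down.b")]] <- rep(0, c_out)
        params[[paste0(pre, "down.bn.gamma")]] <- rep(1, c_out)
        params[[paste0(pre, "down.bn.beta")]] <- rep(0, c_out)
      }
      c_in <- c_out
    }
  }
  params[["head.W"]] <- glorot(widths[4], 2)
  params[["head.b"]] <- rep(0, 2)

  fwd <- function(params, prep, cfg, training = FALSE, buffers = NULL) {
    B <- prep$B
    H <- prep$H
    W_sp <- prep$W
    h <- ag_conv2d(as_ag_x(prep), params[["stem.W"]], params[["stem.b"]],
                   stride = 2L, pad = 3L, B, H, W_sp)
    H <- attr(h, "H_out"); W_sp <- attr(h, "W_out")
    h <- ag_relu(ag_batchnorm(h, params[["stem.bn.gamma"]],
                              params[["stem.bn.beta"]], buffers,
                              "stem.bn", training))
    h <- ag_maxpool2d(h, B, H, W_sp, k = 3, stride = 2, pad = 1)
    H <- attr(h, "H_out"); W_sp <- attr(h, "W_out")
    for (s in seq_along(blocks)) {
      for (bl in seq_len(blocks[s])) {
        pre <- sprintf("s%d.b%d.", s, bl)
        stride1 <- if (bl == 1 && s > 1) 2L else 1L
        identity <- h
        out <- ag_conv2d(h, params[[paste0(pre, "conv1.W")]],
                         params[[paste0(pre, "conv1.b")]],
                         stride = stride1, pad = 1L, B, H, W_sp)
        H2 <- attr(out, "H_out"); W2 <- attr(out, "W_out")
        out <- ag_relu(ag_batchnorm(out, params[[paste0(pre, "bn1.gamma")]],
                                    params[[paste0(pre, "bn1.beta")]],
                                    buffers, paste0(pre, "bn1"), training))
        out <- ag_conv2d(out, params[[paste0(pre, "conv2.W")]],
                         params[[paste0(pre, "conv2.b")]],
                         stride = 1L, pad = 1L, B, H2, W2)
        out <- ag_batchnorm(out, params[[paste0(pre, "bn2.gamma")]],
                            params[[paste0(pre, "bn2.beta")]],
                            buffers, paste0(pre, "bn2"), training)
        if (!is.null(params[[paste0(pre, "down.W")]])) {
          identity <- ag_conv2d(h, params[[paste0(pre, "down.W")]],
                                params[[paste0(pre, "down.b")]],
                                stride = stride1, pad = 0L, B, H, W_sp)
          identity <- ag_batchnorm(identity,
                                   params[[paste0(pre, "down.bn.gamma")]],
                                   params[[paste0(pre, "down.bn.beta")]],
                                   buffers, paste0(pre, "down.bn"), training)
        }
        h <- ag_relu(ag_add(out, identity))
        H <- H2; W_sp <- W2
      }
    }
    pooled <- ag_global_avgpool2d(h, B, H * W_sp)
    ag_add_bias(ag_matmul(pooled, params[["head.W"]]), params[["head.b"]])
  }
  new_bs_model("resnet34", params, spec, fwd, prepare_image)
}

# stack tl x n_coeffs matrices as one-channel images, row-major per sample
prepare_image <- function(features_list) {
  mats <- lapply(features_list, function(f) {
    if (inherits(f, "bs_features")) f$values else f
  })
  H <- nrow(mats[[1]])
  W_sp <- ncol(mats[[1]])
  x <- matrix(unlist(lapply(mats, function(m) as.numeric(t(m)))), ncol = 1)
  list(x = x, B = length(mats), H = H, W = W_sp, T = H * W_sp)
}
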