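#' Branchformer encoder configuration
#'
#' All architecture hyperparameters of the encoder. Each block runs a
#' global branch (pre-norm multi-head self-attention) and a local branch
#' (convolutional-gating MLP) in parallel and merges them; a convolutional
#' frontend first downsamples the feature sequence in time.
#'
#' @param d Model width (must be divisible by `n_heads`).
#' @param n_blocks Number of stacked identical blocks.
#' @param n_heads Attention heads.
#' @param d_inter Inner width of the cgMLP (must be even; it is split into
#'   the gate half A and the convolved half B). Default `4 * d`.
#' @param kernel_size Depth-wise convolution length (odd).
#' @param dropout_rate Dropout probability on each branch output.
#' @param branch_dropout_rate Probability, during training, of zeroing one
#'   randomly chosen branch before merging.
#' @param merge_mode `"concat"` (concatenate then project, the default) or
#'   `"weighted_average"` (learned softmax weights over the two branches).
#' @param subsample_factor Temporal downsampling of the frontend (2 or 4).
#' @return A `bs_encoder_config` list.
#' @export
encoder_config <- function(d = 64, n_blocks = 6, n_heads = 4,
                           d_inter = 4 * d, kernel_size = 31,
                           dropout_rate = 0.1, branch_dropout_rate = 0.1,
                           merge_mode = c("concat", "weighted_average"),
                           subsample_factor = 4) {
  merge_mode <- match.arg(merge_mode)
  stopifnot(d %% n_heads == 0, d_inter %% 2 == 0,
            dropout_rate >= 0, dropout_rate < 1,
            branch_dropout_rate >= 0, branch_dropout_rate < 1,
            subsample_factor %in% c(2, 4))
  structure(
    list(d = d, n_blocks = n_blocks, n_heads = n_heads, d_inter = d_inter,
         kernel_size = kernel_size, dropout_rate = dropout_rate,
         branch_dropout_rate = branch_dropout_rate, merge_mode = merge_mode,
         subsample_factor = subsample_factor),
    class = "bs_encoder_config"
  )
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialise the parameters of one Branchformer block
#'
#' Tensor shapes: attention projections `Wq, Wk, Wv, Wo` are `d x d`; the
#' cgMLP up-projection `U` is `d x d_inter` and down-projection `Vproj` is
#' `(d_inter/2) x d`; the depth-wise kernel is `kernel_size x d_inter/2`
#' (one kernel per channel, no cross-channel mixing); the concat-merge
#' projection `merge.W` is `2d x d`. Layer norms carry a scale and offset
#' each. Projections inside the block are bias-free.
#'
#' @param cfg A [encoder_config()].
#' @return Named list of parameter arrays.
#' @export
block_params <- function(cfg) {
  d <- cfg$d
  di <- cfg$d_inter
  dh <- di / 2
  p <- list(
    Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
    Wo = glorot(d, d),
    ln_attn.gamma = rep(1, d), ln_attn.beta = rep(0, d),
    ln_cgmlp.gamma = rep(1, d), ln_cgmlp.beta = rep(0, d),
    U = glorot(d, di),
    ln_b.gamma = rep(1, dh), ln_b.beta = rep(0, dh),
    dw.kernel = matrix(stats::runif(cfg$kernel_size * dh,
                                    -sqrt(3 / cfg$kernel_size),
                                    sqrt(3 / cfg$kernel_size)),
                       cfg$kernel_size, dh),
    Vproj = glorot(dh, d)
  )
  if (cfg$merge_mode == "concat") {
    p$merge.W <- glorot(2 * d, d)
  } else {
    p$merge.theta <- c(0, 0)
  }
  p
}

#' Initialise a Branchformer classifier
#'
#' Builds the full parameter set: a two-convolution temporal subsampling
#' frontend mapping `n_coeffs`-dimensional feature frames to width `d`, `N`
#' identical blocks (independent parameters, identical shapes), a final
#' layer norm, and a 2-class linear head applied to the time-mean of the
#' encoded sequence.
#'
#' @param n_coeffs Number of feature coefficients per frame.
#' @param cfg A [encoder_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return A `bs_model` object.
#' @export
init_branchformer <- function(n_coeffs, cfg = encoder_config(), seed = 1) {
  withr::local_seed(seed)
  d <- cfg$d
  params <- list()
  if (cfg$subsample_factor == 4) {
    params[["sub1.W"]] <- glorot(3 * n_coeffs, d)
    params[["sub1.b"]] <- rep(0, d)
    params[["sub2.W"]] <- glorot(3 * d, d)
    params[["sub2.b"]] <- rep(0, d)
  } else {
    params[["sub1.W"]] <- glorot(3 * n_coeffs, d)
    params[["sub1.b"]] <- rep(0, d)
  }
  for (i in seq_len(cfg$n_blocks)) {
    bp <- block_params(cfg)
    names(bp) <- paste0("blk", i, ".", names(bp))
    params <- c(params, bp)
  }
  params[["final_ln.gamma"]] <- rep(1, d)
  params[["final_ln.beta"]] <- rep(0, d)
  params[["head.W"]] <- glorot(d, 2)
  params[["head.b"]] <- rep(0, 2)
  new_bs_model("branchformer", params, cfg,
               forward = bf_forward_ag, prepare = prepare_sequence,
               meta = list(n_coeffs = n_coeffs))
}

new_bs_model <- function(family, params, cfg, forward, prepare,
                         meta = list()) {
  structure(
    list(family = family, params = params, cfg = cfg,
         buffers = new.env(parent = emptyenv()),
         forward = forward, prepare = prepare, meta = meta),
    class = "bs_model"
  )
}

#' @export
print.bs_model <- function(x, ...) {
  cat(sprintf("<bs_model %s: %d parameter tensors, %d parameters>\n",
              x$family, length(x$params), n_model_params(x)))
  invisible(x)
}

#' Total number of scalar parameters in a model
#' @param model A `bs_model`.
#' @return Integer count.
#' @export
n_model_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# stack a list of tl x n_coeffs feature matrices sample-contiguously
prepare_sequence <- function(features_list) {
  mats <- lapply(features_list, function(f) {
    if (inherits(f, "bs_features")) f$values else f
  })
  T <- nrow(mats[[1]])
  list(x = do.call(rbind, mats), B = length(mats), T = T)
}

params_to_ag <- function(params, trainable = NULL) {
  out <- lapply(names(params), function(nm) {
    ag(params[[nm]],
       requires_grad = is.null(trainable) || nm %in% trainable)
  })
  names(out) <- names(params)
  out
}

subblock <- function(p, i) {
  pre <- paste0("blk", i, ".")
  sel <- startsWith(names(p), pre)
  out <- p[sel]
  names(out) <- substring(names(out), nchar(pre) + 1)
  out
}

# ---- internal graph builders (ag in, ag out) ----------------------------

bf_subsample_ag <- function(x, p, cfg, B, T) {
  h <- ag_relu(ag_conv1d(x, p[["sub1.W"]], p[["sub1.b"]], 2L, B, T))
  T1 <- ceiling(T / 2)
  if (cfg$subsample_factor == 4) {
    h <- ag_relu(ag_conv1d(h, p[["sub2.W"]], p[["sub2.b"]], 2L, B, T1))
    T1 <- ceiling(T1 / 2)
  }
  list(x = h, T = T1)
}

bf_global_ag <- function(x, p, cfg, B, T, training, use_layernorm = TRUE) {
  h <- if (use_layernorm) {
    ag_layernorm(x, p[["ln_attn.gamma"]], p[["ln_attn.beta"]])
  } else x
  h <- ag_mhsa(h, p[["Wq"]], p[["Wk"]], p[["Wv"]], p[["Wo"]],
               B, T, cfg$n_heads)
  ag_dropout(h, cfg$dropout_rate, training)
}

bf_csgu_ag <- function(z, p, B, T, use_layernorm = TRUE) {
  di <- ncol(z$value)
  if (di %% 2 != 0) stop("d_inter must be even", call. = FALSE)
  half <- di / 2
  a <- ag_slice_cols(z, seq_len(half))
  b <- ag_slice_cols(z, (half + 1):di)
  bn <- if (use_layernorm) {
    ag_layernorm(b, p[["ln_b.gamma"]], p[["ln_b.beta"]])
  } else b
  conv <- ag_dwconv_time(bn, p[["dw.kernel"]], B, T)
  ag_mul(a, conv)
}

bf_local_ag <- function(x, p, cfg, B, T, training, use_layernorm = TRUE) {
  h <- if (use_layernorm) {
    ag_layernorm(x, p[["ln_cgmlp.gamma"]], p[["ln_cgmlp.beta"]])
  } else x
  z <- ag_gelu(ag_matmul(h, p[["U"]]))
  zt <- bf_csgu_ag(z, p, B, T, use_layernorm)
  y <- ag_matmul(zt, p[["Vproj"]])
  ag_dropout(y, cfg$dropout_rate, training)
}

bf_merge_ag <- function(yg, yl, p, mode) {
  if (!identical(dim(yg$value), dim(yl$value))) {
    stop("branch outputs have mismatched shapes", call. = FALSE)
  }
  if (mode == "concat") {
    ag_matmul(ag_concat_cols(yg, yl), p[["merge.W"]])
  } else {
    w <- ag_softmax_vec(p[["merge.theta"]])
    ag_weighted_sum(yg, yl, w)
  }
}

bf_block_ag <- function(x, p, cfg, B, T, training) {
  yg <- bf_global_ag(x, p, cfg, B, T, training)
  yl <- bf_local_ag(x, p, cfg, B, T, training)
  if (training && cfg$branch_dropout_rate > 0 &&
      stats::runif(1) < cfg$branch_dropout_rate) {
    if (stats::runif(1) < 0.5) {
      yg <- ag_scale(yg, 0)
    } else {
      yl <- ag_scale(yl, 0)
    }
  }
  ag_add(x, bf_merge_ag(yg, yl, p, cfg$merge_mode))
}

bf_forward_ag <- function(params, prep, cfg, training = FALSE,
                          buffers = NULL) {
  sub <- bf_subsample_ag(as_ag_x(prep), params, cfg, prep$B, prep$T)
  h <- sub$x
  T <- sub$T
  for (i in seq_len(cfg$n_blocks)) {
    h <- bf_block_ag(h, subblock(params, i), cfg, prep$B, T, training)
  }
  h <- ag_layernorm(h, params[["final_ln.gamma"]], params[["final_ln.beta"]])
  pooled <- ag_mean_pool_time(h, prep$B, T)
  ag_add_bias(ag_matmul(pooled, params[["head.W"]]), params[["head.b"]])
}

as_ag_x <- function(prep) if (is_ag(prep$x)) prep$x else ag(prep$x)

# ---- public single-sequence operations ----------------------------------

#' Temporal subsampling frontend
#'
#' Two (or one, for `subsample_factor = 2`) stride-2 same-padded
#' convolutions with ReLU, mapping a `tl x n_coeffs` feature matrix to a
#' `T x d` hidden sequence with `T = ceiling(ceiling(tl/2)/2)`.
#'
#' @param features A `bs_features` object or `tl x n_coeffs` matrix.
#' @param model A Branchformer `bs_model`.
#' @return A `T x d` matrix.
#' @export
conv_subsample <- function(features, model) {
  x <- if (inherits(features, "bs_features")) features$values else features
  if (nrow(x) < model$cfg$subsample_factor) {
    stop("feature length (", nrow(x), ") shorter than the subsampling ",
         "factor", call. = FALSE)
  }
  p <- params_to_ag(model$params, trainable = character(0))
  sub <- bf_subsample_ag(ag(x), p, model$cfg, 1L, nrow(x))
  sub$x$value
}

#' Global extractor branch (pre-norm multi-head self-attention)
#'
#' Layer norm, multi-head scaled dot-product self-attention
#' (`softmax(Q K' / sqrt(d/n_heads)) V` per head, then an output
#' projection), and dropout (active only during training).
#'
#' @param X A `T x d` hidden sequence matrix.
#' @param p Block parameters ([block_params()]).
#' @param n_heads Number of attention heads.
#' @param training Logical; enables dropout.
#' @param dropout_rate Dropout probability when training.
#' @param use_layernorm Set `FALSE` to bypass the pre-norm (testing hook).
#' @return A `T x d` matrix `Y_G`.
#' @export
global_branch <- function(X, p, n_heads = 1, training = FALSE,
                          dropout_rate = 0, use_layernorm = TRUE) {
  cfg <- list(n_heads = n_heads, dropout_rate = dropout_rate)
  pa <- params_to_ag(p, trainable = character(0))
  bf_global_ag(ag(X), pa, cfg, 1L, nrow(X), training, use_layernorm)$value
}

#' Convolutional spatial gating unit
#'
#' Splits the channels of `Z` into halves `A` and `B` and returns
#' `A * DwConv(LN(B))`: the first half gates a depth-wise (per-channel,
#' same-padded) temporal convolution of the layer-normalised second half.
#'
#' @param Z A `T x d_inter` matrix (`d_inter` even).
#' @param p Block parameters with `dw.kernel` (`kernel_size x d_inter/2`)
#'   and `ln_b.gamma` / `ln_b.beta`.
#' @param use_layernorm Set `FALSE` to bypass the norm (testing hook).
#' @return A `T x d_inter/2` matrix.
#' @export
csgu <- function(Z, p, use_layernorm = TRUE) {
  pa <- params_to_ag(p, trainable = character(0))
  bf_csgu_ag(ag(Z), pa, 1L, nrow(Z), use_layernorm)$value
}

#' Local extractor branch (cgMLP)
#'
#' `Z = GELU(LN(X) U)`, gated by the convolutional spatial gating unit,
#' then projected back to width `d`:
#' `Y_L = Dropout(CSGU(Z) Vproj)`.
#'
#' @inheritParams global_branch
#' @return A `T x d` matrix `Y_L`.
#' @export
local_branch <- function(X, p, training = FALSE, dropout_rate = 0,
                         use_layernorm = TRUE) {
  cfg <- list(dropout_rate = dropout_rate)
  pa <- params_to_ag(p, trainable = character(0))
  bf_local_ag(ag(X), pa, cfg, 1L, nrow(X), training, use_layernorm)$value
}

#' Merge the global and local branch outputs
#'
#' Concat mode concatenates the branches along channels and projects with
#' `W` (`2d x d`); weighted mode forms `w_G Y_G + w_L Y_L` with softmax
#' weights generated from the learned scalar pair `merge.theta`.
#'
#' @param Y_G,Y_L `T x d` branch outputs.
#' @param p Block parameters.
#' @param mode `"concat"` or `"weighted_average"`.
#' @param weights Optional fixed nonnegative weight pair summing to 1 for
#'   weighted mode, bypassing the learned `merge.theta`.
#' @return A `T x d` matrix.
#' @export
merge_branches <- function(Y_G, Y_L, p, mode = "concat", weights = NULL) {
  if (!identical(dim(Y_G), dim(Y_L))) {
    stop("branch outputs have mismatched shapes", call. = FALSE)
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == 2, all(weights >= 0),
              abs(sum(weights) - 1) < 1e-8)
    return(weights[1] * Y_G + weights[2] * Y_L)
  }
  pa <- params_to_ag(p, trainable = character(0))
  bf_merge_ag(ag(Y_G), ag(Y_L), pa, mode)$value
}

#' One full Branchformer block
#'
#' `X + Merge(GlobalBranch(X), LocalBranch(X))` with a residual connection.
#' During training, with probability `branch_dropout_rate` one branch
#' (chosen uniformly) is zeroed before merging; inference never drops a
#' branch and is deterministic.
#'
#' @param X A `T x d` matrix.
#' @param p Block parameters.
#' @param cfg An [encoder_config()].
#' @param training Logical.
#' @return A `T x d` matrix.
#' @export
branchformer_block <- function(X, p, cfg, training = FALSE) {
  pa <- params_to_ag(p, trainable = character(0))
  bf_block_ag(ag(X), pa, cfg, 1L, nrow(X), training)$value
}

#' Encode a feature matrix and classify it
#'
#' Runs the frontend, the stacked blocks, a final layer norm, mean pooling
#' over time, and the 2-class linear head; returns softmax probabilities.
#'
#' @param features A `bs_features` object or `tl x n_coeffs` matrix.
#' @param model A Branchformer `bs_model`.
#' @param training Logical; enables dropout and branch dropout.
#' @return Numeric vector of 2 class probabilities (non-event, event).
#' @export
encode_and_classify <- function(features, model, training = FALSE) {
  x <- if (inherits(features, "bs_features")) features$values else features
  prep <- list(x = x, B = 1L, T = nrow(x))
  p <- params_to_ag(model$params, trainable = character(0))
  logits <- model$forward(p, prep, model$cfg, training,
                          buffers = model$buffers)$value
  drop(softmax_rows(logits))
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Class probabilities for a batch of feature matrices
#'
#' @param model A `bs_model`.
#' @param features_list List of `bs_features` objects (or matrices), all
#'   with the same number of frames.
#' @return A `B x 2` matrix of probabilities.
#' @export
predict_proba <- function(model, features_list) {
  prep <- model$prepare(features_list)
  p <- params_to_ag(model$params, trainable = character(0))
  logits <- model$forward(p, prep, model$cfg, FALSE,
                          buffers = model$buffers)$value
  softmax_rows(logits)
}

#' Predicted class labels (0 = non-event, 1 = bowel-sound event)
#' @inheritParams predict_proba
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, features_list) {
  as.integer(apply(predict_proba(model, features_list), 1, which.max) - 1L)
}
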