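# Reverse-mode automatic differentiation on a dynamically built tape.
#
# Every node is an environment holding a value (numeric vector / matrix),
# an accumulated gradient, its parents, and a backward closure returning
# the gradients to propagate to each parent. Model forward passes build the
# graph; ag_backward() runs a topological sweep. Parameters are wrapped
# fresh at every training step, so gradients never leak across steps.
#
# Batched sequences are laid out sample-contiguously: a batch of B
# sequences of T frames and C channels is one (B*T) x C matrix whose rows
# (b-1)*T + 1 .. b*T belong to sample b. Ops that need the sequence
# structure (attention, depth-wise convolution, subsampling, LSTM) take B
# and T explicitly; purely row-wise ops (linear, layer norm, activations)
# are batch-transparent.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

#' Wrap a value as an autodiff node
#'
#' @param value Numeric vector, matrix or array.
#' @param requires_grad Should gradients be accumulated for this node?
#' @return An `ag_node`.
#' @keywords internal
#' @export
ag <- function(value, requires_grad = FALSE) {
  node <- new.env(parent = emptyenv())
  .ag_env$counter <- .ag_env$counter + 1L
  node$id <- .ag_env$counter
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$backfn <- NULL
  node$requires_grad <- requires_grad
  class(node) <- "ag_node"
  node
}

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag(x)

ag_op <- function(value, parents, backfn) {
  need <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  node <- ag(value, requires_grad = need)
  if (need) {
    node$parents <- parents
    node$backfn <- backfn
  }
  node
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into every upstream node with
#' `requires_grad = TRUE`.
#'
#' @param loss An `ag_node` holding a scalar.
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  # iterative DFS for a topological order (graphs can be deep: LSTM, ResNet)
  topo <- vector("list", 256)
  n_topo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires_grad && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
    }
  }
  loss$grad <- array(1, dim = dim(loss$value) %||% 1)
  if (length(loss$value) != 1) {
    stop("ag_backward expects a scalar loss", call. = FALSE)
  }
  for (i in n_topo:1) {
    node <- topo[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    grads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      g <- grads[[j]]
      if (!p$requires_grad || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# ---- elementwise and linear-algebra primitives --------------------------

ag_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_add_bias <- function(x, b) {
  # x: n x C matrix; b: length-C bias broadcast over rows
  ag_op(sweep(x$value, 2, b$value, `+`), list(x, b),
        function(g) list(g, colSums(g)))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {
  ag_op(a$value * s, list(a), function(g) list(g * s))
}

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), crossprod(av, g)))
}

ag_gelu <- function(x) {
  xv <- x$value
  ag_op(xv * stats::pnorm(xv), list(x),
        function(g) list(g * (stats::pnorm(xv) + xv * stats::dnorm(xv))))
}

ag_relu <- function(x) {
  xv <- x$value
  ag_op(pmax(xv, 0) * 1, list(x), function(g) list(g * (xv > 0)))
}

ag_tanh <- function(x) {
  y <- tanh(x$value)
  ag_op(y, list(x), function(g) list(g * (1 - y^2)))
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  ag_op(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_concat_cols <- function(a, b) {
  na <- ncol(a$value)
  ag_op(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ag_slice_cols <- function(x, cols) {
  nc <- ncol(x$value)
  ag_op(x$value[, cols, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(g), nc)
    gx[, cols] <- g
    list(gx)
  })
}

ag_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= rate) /
    (1 - rate)
  ag_op(x$value * mask, list(x), function(g) list(g * mask))
}

# ---- normalisation ------------------------------------------------------

ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- gamma$value
  out <- sweep(sweep(xhat, 2, gv, `*`), 2, beta$value, `+`)
  ag_op(out, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, gv, `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

ag_batchnorm <- function(x, gamma, beta, buffers, name, training,
                         momentum = 0.1, eps = 1e-5) {
  # x: n x C; channel statistics over all rows (batch and spatial positions)
  xv <- x$value
  gv <- gamma$value
  if (training) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2, mu)
    v <- colMeans(xc^2)
    # update running statistics (side channel, outside the tape)
    buffers[[paste0(name, ".mean")]] <-
      (1 - momentum) * (buffers[[paste0(name, ".mean")]] %||% 0) + momentum * mu
    buffers[[paste0(name, ".var")]] <-
      (1 - momentum) * (buffers[[paste0(name, ".var")]] %||% 1) + momentum * v
  } else {
    mu <- buffers[[paste0(name, ".mean")]] %||% numeric(ncol(xv))
    v <- buffers[[paste0(name, ".var")]] %||% rep(1, ncol(xv))
    xc <- sweep(xv, 2, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, gv, `*`), 2, beta$value, `+`)
  n <- nrow(xv)
  ag_op(out, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, gv, `*`)
    if (training) {
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * xhat)
      dx <- sweep(dxhat - rep(m1, each = n) - xhat * rep(m2, each = n),
                  2, inv, `*`)
    } else {
      dx <- sweep(dxhat, 2, inv, `*`)
    }
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# ---- losses and pooling -------------------------------------------------

ag_softmax_cross_entropy <- function(logits, y) {
  # logits: B x K; y: integer class labels in 1..K; mean cross-entropy
  lv <- logits$value
  m <- apply(lv, 1, max)
  e <- exp(lv - m)
  p <- e / rowSums(e)
  B <- nrow(lv)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  ag_op(loss, list(logits), function(g) {
    dp <- p
    dp[idx] <- dp[idx] - 1
    list(dp * as.numeric(g) / B)
  })
}

ag_mean_pool_time <- function(x, B, T) {
  grp <- rep(seq_len(B), each = T)
  out <- rowsum(x$value, grp) / T
  ag_op(out, list(x), function(g) list(g[grp, , drop = FALSE] / T))
}

ag_rows_softmax <- function(x) {
  xv <- x$value
  m <- apply(xv, 1, max)
  e <- exp(xv - m)
  s <- e / rowSums(e)
  ag_op(s, list(x), function(g) {
    gs <- g * s
    list(gs - s * rowSums(gs))
  })
}

ag_softmax_vec <- function(x) {
  e <- exp(x$value - max(x$value))
  s <- e / sum(e)
  ag_op(s, list(x), function(g) {
    gs <- g * s
    list(gs - s * sum(gs))
  })
}

ag_weighted_sum <- function(a, b, w) {
  # w: ag node with two nonnegative weights
  wv <- w$value
  av <- a$value; bv <- b$value
  ag_op(wv[1] * av + wv[2] * bv, list(a, b, w), function(g) {
    list(g * wv[1], g * wv[2], c(sum(g * av), sum(g * bv)))
  })
}

# ---- fused multi-head self-attention ------------------------------------

ag_mhsa <- function(x, Wq, Wk, Wv, Wo, B, T, n_heads) {
  # x: (B*T) x d, sample-contiguous rows; projections d x d, no biases
  d <- ncol(x$value)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  xv <- x$value
  Q <- xv %*% Wq$value
  K <- xv %*% Wk$value
  V <- xv %*% Wv$value
  Ocat <- matrix(0, B * T, d)
  Pcache <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      S <- tcrossprod(Qh, Kh) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      P <- E / rowSums(E)
      Pcache[[(b - 1) * n_heads + h]] <- P
      Ocat[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- Ocat %*% Wo$value
  ag_op(out, list(x, Wq, Wk, Wv, Wo), function(g) {
    dOcat <- g %*% t(Wo$value)
    dWo <- crossprod(Ocat, g)
    dQ <- matrix(0, B * T, d)
    dK <- matrix(0, B * T, d)
    dV <- matrix(0, B * T, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        P <- Pcache[[(b - 1) * n_heads + h]]
        dOh <- dOcat[rows, cols, drop = FALSE]
        Vh <- V[rows, cols, drop = FALSE]
        dP <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(P, dOh)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, cols] <- (dS %*% K[rows, cols, drop = FALSE]) * scale
        dK[rows, cols] <- (crossprod(dS, Q[rows, cols, drop = FALSE])) * scale
      }
    }
    dx <- dQ %*% t(Wq$value) + dK %*% t(Wk$value) + dV %*% t(Wv$value)
    list(dx, crossprod(xv, dQ), crossprod(xv, dK), crossprod(xv, dV), dWo)
  })
}

# ---- convolutions -------------------------------------------------------

ag_dwconv_time <- function(x, kernel, B, T) {
  # depth-wise convolution along time, same padding, one kernel per channel
  # x: (B*T) x C; kernel: K x C
  kv <- kernel$value
  K <- nrow(kv)
  C <- ncol(kv)
  pad_l <- (K - 1) %/% 2
  xv <- x$value
  out <- matrix(0, B * T, C)
  # arrange as padded 3D array (T + K - 1) x C x B for vectorised shifts
  arr <- array(0, dim = c(T + K - 1, C, B))
  for (b in seq_len(B)) {
    arr[pad_l + seq_len(T), , b] <- xv[((b - 1) * T + 1):(b * T), ,
                                       drop = FALSE]
  }
  acc <- array(0, dim = c(T, C, B))
  for (k in seq_len(K)) {
    acc <- acc + arr[k:(k + T - 1), , , drop = FALSE] *
      rep(kv[k, ], each = T)
  }
  for (b in seq_len(B)) {
    out[((b - 1) * T + 1):(b * T), ] <- acc[, , b]
  }
  ag_op(out, list(x, kernel), function(g) {
    garr <- array(0, dim = c(T, C, B))
    for (b in seq_len(B)) {
      garr[, , b] <- g[((b - 1) * T + 1):(b * T), , drop = FALSE]
    }
    gpad <- array(0, dim = c(T + K - 1, C, B))
    dk <- matrix(0, K, C)
    for (k in seq_len(K)) {
      seg <- arr[k:(k + T - 1), , , drop = FALSE]
      dk[k, ] <- apply(garr * seg, 2, sum)
      gpad[k:(k + T - 1), , ] <- gpad[k:(k + T - 1), , , drop = FALSE] +
        garr * rep(kv[k, ], each = T)
    }
    dx <- matrix(0, B * T, C)
    for (b in seq_len(B)) {
      dx[((b - 1) * T + 1):(b * T), ] <- gpad[pad_l + seq_len(T), , b]
    }
    list(dx, dk)
  })
}

conv1d_geometry <- function(T, K, stride) {
  T_out <- ceiling(T / stride)
  pad_total <- max(0, (T_out - 1) * stride + K - T)
  pad_l <- pad_total %/% 2
  src <- matrix(0L, T_out, K)        # 0 marks a zero-padded position
  for (t0 in seq_len(T_out)) {
    pos <- (t0 - 1) * stride + seq_len(K) - pad_l
    pos[pos < 1 | pos > T] <- 0L
    src[t0, ] <- pos
  }
  list(T_out = T_out, src = src)
}

ag_conv1d <- function(x, W, b, stride, B, T) {
  # x: (B*T) x Cin; W: (K*Cin) x Cout; same padding, output length ceil(T/s)
  Cin <- ncol(x$value)
  K <- nrow(W$value) / Cin
  geo <- conv1d_geometry(T, K, stride)
  T_out <- geo$T_out
  xv <- x$value
  x_ext <- rbind(xv, 0)                       # last row = zero pad source
  zrow <- nrow(x_ext)
  # global row indices for all samples / output frames / kernel taps
  idx <- matrix(0L, B * T_out, K)
  for (b_i in seq_len(B)) {
    off <- (b_i - 1) * T
    block <- geo$src
    block[block > 0] <- block[block > 0] + off
    block[block == 0] <- zrow
    idx[((b_i - 1) * T_out + 1):(b_i * T_out), ] <- block
  }
  patches <- matrix(0, B * T_out, K * Cin)
  for (k in seq_len(K)) {
    patches[, ((k - 1) * Cin + 1):(k * Cin)] <- x_ext[idx[, k], , drop = FALSE]
  }
  out <- sweep(patches %*% W$value, 2, b$value, `+`)
  ag_op(out, list(x, W, b), function(g) {
    dW <- crossprod(patches, g)
    db <- colSums(g)
    dpatch <- g %*% t(W$value)
    dx <- matrix(0, B * T + 1, Cin)
    for (k in seq_len(K)) {
      part <- dpatch[, ((k - 1) * Cin + 1):(k * Cin), drop = FALSE]
      tgt <- idx[, k]
      keep <- tgt != zrow
      # within one tap, target rows are distinct, so plain indexing is safe
      dx[tgt[keep], ] <- dx[tgt[keep], , drop = FALSE] +
        part[keep, , drop = FALSE]
    }
    list(dx[seq_len(B * T), , drop = FALSE], dW, db)
  })
}

conv2d_geometry <- function(H, W_sp, kh, kw, stride, pad) {
  H_out <- (H + 2 * pad - kh) %/% stride + 1
  W_out <- (W_sp + 2 * pad - kw) %/% stride + 1
  n_out <- H_out * W_out
  src <- matrix(0L, n_out, kh * kw)
  o <- 1L
  for (ho in seq_len(H_out)) {
    for (wo in seq_len(W_out)) {
      t <- 1L
      for (dh in seq_len(kh)) {
        hh <- (ho - 1) * stride + dh - pad
        for (dw in seq_len(kw)) {
          ww <- (wo - 1) * stride + dw - pad
          src[o, t] <- if (hh >= 1 && hh <= H && ww >= 1 && ww <= W_sp) {
            (hh - 1L) * W_sp + ww
          } else 0L
          t <- t + 1L
        }
      }
      o <- o + 1L
    }
  }
  list(H_out = H_out, W_out = W_out, src = src)
}

ag_conv2d <- function(x, W, b, stride, pad, B, H, W_sp) {
  # x: (B*H*W_sp) x Cin, row-major spatial layout per sample
  Cin <- ncol(x$value)
  KK <- nrow(W$value) / Cin
  kh <- as.integer(round(sqrt(KK)))
  kw <- KK / kh
  geo <- conv2d_geometry(H, W_sp, kh, kw, stride, pad)
  n_out <- geo$H_out * geo$W_out
  xv <- x$value
  x_ext <- rbind(xv, 0)
  zrow <- nrow(x_ext)
  HW <- H * W_sp
  idx <- matrix(0L, B * n_out, KK)
  for (b_i in seq_len(B)) {
    block <- geo$src
    block[block > 0] <- block[block > 0] + (b_i - 1L) * HW
    block[block == 0] <- zrow
    idx[((b_i - 1) * n_out + 1):(b_i * n_out), ] <- block
  }
  patches <- matrix(0, B * n_out, KK * Cin)
  for (k in seq_len(KK)) {
    patches[, ((k - 1) * Cin + 1):(k * Cin)] <- x_ext[idx[, k], , drop = FALSE]
  }
  out <- sweep(patches %*% W$value, 2, b$value, `+`)
  res <- ag_op(out, list(x, W, b), function(g) {
    dW <- crossprod(patches, g)
    db <- colSums(g)
    dpatch <- g %*% t(W$value)
    dx <- matrix(0, B * HW + 1, Cin)
    for (k in seq_len(KK)) {
      part <- dpatch[, ((k - 1) * Cin + 1):(k * Cin), drop = FALSE]
      tgt <- idx[, k]
      keep <- tgt != zrow
      dx[tgt[keep], ] <- dx[tgt[keep], , drop = FALSE] +
        part[keep, , drop = FALSE]
    }
    list(dx[seq_len(B * HW), , drop = FALSE], dW, db)
  })
  attr(res, "H_out") <- geo$H_out
  attr(res, "W_out") <- geo$W_out
  res
}

ag_maxpool2d <- function(x, B, H, W_sp, k = 3, stride = 2, pad = 1) {
  C <- ncol(x$value)
  geo <- conv2d_geometry(H, W_sp, k, k, stride, pad)
  n_out <- geo$H_out * geo$W_out
  xv <- x$value
  x_ext <- rbind(xv, -Inf)
  zrow <- nrow(x_ext)
  HW <- H * W_sp
  KK <- k * k
  idx <- matrix(0L, B * n_out, KK)
  for (b_i in seq_len(B)) {
    block <- geo$src
    block[block > 0] <- block[block > 0] + (b_i - 1L) * HW
    block[block == 0] <- zrow
    idx[((b_i - 1) * n_out + 1):(b_i * n_out), ] <- block
  }
  out <- matrix(-Inf, B * n_out, C)
  amax <- matrix(1L, B * n_out, C)      # which tap supplied the max
  for (kk in seq_len(KK)) {
    cand <- x_ext[idx[, kk], , drop = FALSE]
    upd <- cand > out
    amax[upd] <- kk
    out[upd] <- cand[upd]
  }
  out[!is.finite(out)] <- 0
  res <- ag_op(out, list(x), function(g) {
    dx <- matrix(0, B * HW + 1, C)
    for (kk in seq_len(KK)) {
      sel <- amax == kk
      if (!any(sel)) next
      rows_k <- idx[, kk]
      contrib <- g * sel
      # accumulate by source row; duplicates across output positions exist
      nz <- which(rowSums(sel) > 0)
      for (r in nz) {
        tr <- rows_k[r]
        if (tr == zrow) next
        dx[tr, ] <- dx[tr, ] + contrib[r, ]
      }
    }
    list(dx[seq_len(B * HW), , drop = FALSE])
  })
  attr(res, "H_out") <- geo$H_out
  attr(res, "W_out") <- geo$W_out
  res
}

ag_global_avgpool2d <- function(x, B, HW) {
  grp <- rep(seq_len(B), each = HW)
  out <- rowsum(x$value, grp) / HW
  ag_op(out, list(x), function(g) list(g[grp, , drop = FALSE] / HW))
}

# ---- fused LSTM (backpropagation through time) --------------------------

ag_lstm <- function(x, W, U, b, B, T, return_last = TRUE) {
  # x: (B*T) x F sample-contiguous; W: F x 4H; U: H x 4H; b: 4H
  # gate order: input, forget, output, candidate
  H <- ncol(U$value)
  Hh <- H / 4
  xv <- x$value
  Wv <- W$value; Uv <- U$value; bv <- b$value
  t_rows <- function(t) (0:(B - 1)) * T + t
  h <- matrix(0, B, Hh)
  cc <- matrix(0, B, Hh)
  cache <- vector("list", T)
  h_all <- matrix(0, B * T, Hh)
  pre_x <- xv %*% Wv                   # (B*T) x 4H, all steps at once
  for (t in seq_len(T)) {
    gates <- sweep(pre_x[t_rows(t), , drop = FALSE] + h %*% Uv, 2, bv, `+`)
    i_g <- 1 / (1 + exp(-gates[, 1:Hh, drop = FALSE]))
    f_g <- 1 / (1 + exp(-gates[, (Hh + 1):(2 * Hh), drop = FALSE]))
    o_g <- 1 / (1 + exp(-gates[, (2 * Hh + 1):(3 * Hh), drop = FALSE]))
    g_g <- tanh(gates[, (3 * Hh + 1):(4 * Hh), drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    cache[[t]] <- list(i = i_g, f = f_g, o = o_g, g = g_g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
    h_all[t_rows(t), ] <- h
  }
  out <- if (return_last) h else h_all
  ag_op(out, list(x, W, U, b), function(gout) {
    dh_next <- matrix(0, B, Hh)
    dc_next <- matrix(0, B, Hh)
    dx_pre <- matrix(0, B * T, 4 * Hh)   # gradient wrt pre-activation gates
    dU <- matrix(0, Hh, 4 * Hh)
    db <- numeric(4 * Hh)
    for (t in T:1) {
      ch <- cache[[t]]
      dh <- dh_next
      if (return_last) {
        if (t == T) dh <- dh + gout
      } else {
        dh <- dh + gout[t_rows(t), , drop = FALSE]
      }
      do_g <- dh * ch$tc
      dc <- dc_next + dh * ch$o * (1 - ch$tc^2)
      di <- dc * ch$g
      df <- dc * ch$c_prev
      dg <- dc * ch$i
      dc_next <- dc * ch$f
      dgates <- cbind(di * ch$i * (1 - ch$i),
                      df * ch$f * (1 - ch$f),
                      do_g * ch$o * (1 - ch$o),
                      dg * (1 - ch$g^2))
      dx_pre[t_rows(t), ] <- dgates
      dU <- dU + crossprod(ch$h_prev, dgates)
      db <- db + colSums(dgates)
      dh_next <- dgates %*% t(Uv)
    }
    list(dx_pre %*% t(Wv), crossprod(xv, dx_pre), dU, db)
  })
}
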