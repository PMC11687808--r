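# Independent reference implementations used to cross-check the package.
# These are deliberately naive (double loops, direct solves, full
# enumeration) and share no code with the implementation paths they check.

# scaled dot-product multi-head self-attention, double loop over queries
# and keys; returns list(out, n_score_ops) so tests can count score work
naive_attention <- function(X, Wq, Wk, Wv, Wo, n_heads) {
  T <- nrow(X); d <- ncol(X)
  dh <- d / n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  out <- matrix(0, T, d)
  n_score <- 0
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(T)) {
      scores <- numeric(T)
      for (j in seq_len(T)) {
        scores[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
        n_score <- n_score + 1
      }
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      acc <- numeric(dh)
      for (j in seq_len(T)) acc <- acc + w[j] * V[j, cols]
      out[i, cols] <- acc
    }
  }
  list(out = out %*% Wo, n_score_ops = n_score)
}

# per-channel same-padded 1-D convolution, explicit loops
naive_dwconv <- function(X, kernel) {
  T <- nrow(X); C <- ncol(X)
  K <- nrow(kernel)
  pad <- (K - 1) %/% 2
  out <- matrix(0, T, C)
  n_ops <- 0
  for (c in seq_len(C)) {
    for (t in seq_len(T)) {
      acc <- 0
      for (k in seq_len(K)) {
        src <- t + k - 1 - pad
        if (src >= 1 && src <= T) acc <- acc + kernel[k, c] * X[src, c]
      }
      out[t, c] <- acc
      n_ops <- n_ops + 1
    }
  }
  list(out = out, n_conv_ops = n_ops)
}

# scalar layer norm matching the implementation's epsilon
naive_layernorm <- function(X, gamma, beta, eps = 1e-5) {
  out <- X
  for (i in seq_len(nrow(X))) {
    mu <- mean(X[i, ])
    v <- mean((X[i, ] - mu)^2)
    out[i, ] <- (X[i, ] - mu) / sqrt(v + eps) * gamma + beta
  }
  out
}

naive_gelu <- function(x) x * pnorm(x)

# DCT-II with orthonormal scaling, direct summation
naive_dct <- function(v) {
  N <- length(v)
  out <- numeric(N)
  for (k in 0:(N - 1)) {
    s <- 0
    for (n in 0:(N - 1)) s <- s + v[n + 1] * cos(pi * (2 * n + 1) * k / (2 * N))
    out[k + 1] <- s * sqrt(2 / N) * (if (k == 0) 1 / sqrt(2) else 1)
  }
  out
}

# direct Toeplitz solve of the LPC normal equations
toeplitz_lpc <- function(r, order) {
  R <- stats::toeplitz(r[1:order])
  solve(R, r[2:(order + 1)])
}

# two-sided exact Mann-Whitney p by enumerating every group assignment
perm_mwu_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pool), n)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sliding-index frame counter
count_frames_loop <- function(L, fl, fs) {
  n <- 0
  start <- 1
  while (start + fl - 1 <= L) {
    n <- n + 1
    start <- start + fs
  }
  n
}

# finite-difference gradient of a scalar-valued function of a parameter list
fd_gradient <- function(fn, params, nm, idx, eps = 1e-5) {
  pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
  pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
  (fn(pp) - fn(pm)) / (2 * eps)
}

# small separable two-class feature set: constant mean shift between classes
toy_features <- function(n, tl = 16, n_coeffs = 8, shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    x <- lapply(y, function(lab) {
      matrix(rnorm(tl * n_coeffs, mean = lab * shift), tl, n_coeffs)
    })
    list(x = x, y = y)
  })
}

# minimal 2-channel 16-bit PCM WAV writer for decoder tests
write_stereo_wav <- function(left, right, sr, path) {
  inter <- as.vector(rbind(left, right))
  v <- pmin(pmax(round(inter * 32768), -32768), 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(v) * 2
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(as.integer(v), con, size = 2, endian = "little")
  invisible(path)
}

# block parameters with every tensor fixed to simple known values
identity_block_params <- function(d, d_inter, kernel_size,
                                  merge_mode = "concat") {
  half <- d_inter / 2
  p <- list(
    Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d),
    ln_attn.gamma = rep(1, d), ln_attn.beta = rep(0, d),
    ln_cgmlp.gamma = rep(1, d), ln_cgmlp.beta = rep(0, d),
    U = matrix(0, d, d_inter),
    ln_b.gamma = rep(1, half), ln_b.beta = rep(0, half),
    dw.kernel = matrix(0, kernel_size, half),
    Vproj = matrix(0, half, d)
  )
  if (merge_mode == "concat") p$merge.W <- matrix(0, 2 * d, d)
  else p$merge.theta <- c(0, 0)
  p
}

random_block_params <- function(d, d_inter, kernel_size, seed = 1,
                                merge_mode = "concat") {
  withr::with_seed(seed, {
    half <- d_inter / 2
    p <- list(
      Wq = matrix(rnorm(d * d, sd = 0.3), d),
      Wk = matrix(rnorm(d * d, sd = 0.3), d),
      Wv = matrix(rnorm(d * d, sd = 0.3), d),
      Wo = matrix(rnorm(d * d, sd = 0.3), d),
      ln_attn.gamma = runif(d, 0.5, 1.5), ln_attn.beta = rnorm(d, sd = 0.1),
      ln_cgmlp.gamma = runif(d, 0.5, 1.5),
      ln_cgmlp.beta = rnorm(d, sd = 0.1),
      U = matrix(rnorm(d * d_inter, sd = 0.3), d),
      ln_b.gamma = runif(half, 0.5, 1.5), ln_b.beta = rnorm(half, sd = 0.1),
      dw.kernel = matrix(rnorm(kernel_size * half, sd = 0.3), kernel_size),
      Vproj = matrix(rnorm(half * d, sd = 0.3), half)
    )
    if (merge_mode == "concat") {
      p$merge.W <- matrix(rnorm(2 * d * d, sd = 0.3), 2 * d)
    } else {
      p$merge.theta <- rnorm(2)
    }
    p
  })
}
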