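#' Feature-extraction configuration
#'
#' Holds the knobs shared by the three acoustic feature families. Defaults
#' follow common audio-classification practice: a 40-filter mel bank, 13
#' cepstral coefficients (including coefficient 0), and a 12th-order linear
#' predictor. The FFT size defaults to the next power of two at or above the
#' frame length (frames are zero-padded up to it).
#'
#' @param feature One of `"mel"`, `"mfcc"`, `"lpc"`.
#' @param n_mels Number of triangular mel filters.
#' @param n_mfcc Number of cepstral coefficients kept (`<= n_mels`).
#' @param lpc_order Linear-predictor order (`>= 1`).
#' @param fft_size FFT length in samples, or `NULL` to pick the next power
#'   of two at or above the frame length.
#' @param log_floor Small positive constant added before taking logs.
#' @return A `bs_feature_config` list.
#' @export
feature_config <- function(feature = c("mel", "mfcc", "lpc"),
                           n_mels = 40, n_mfcc = min(13, n_mels),
                           lpc_order = 12, fft_size = NULL,
                           log_floor = 1e-10) {
  feature <- match.arg(feature)
  stopifnot(n_mfcc <= n_mels, lpc_order >= 1, log_floor > 0)
  structure(
    list(feature = feature, n_mels = n_mels, n_mfcc = n_mfcc,
         lpc_order = lpc_order, fft_size = fft_size, log_floor = log_floor),
    class = "bs_feature_config"
  )
}

next_pow2 <- function(n) 2^ceiling(log2(n))

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filter bank
#'
#' Builds `n_mels` triangular filters spaced uniformly on the HTK mel scale
#' (`mel = 2595 log10(1 + f/700)`) between 0 Hz and `sr / 2`, evaluated on
#' the positive-frequency FFT bins. Triangles peak at 1 (no area
#' normalisation).
#'
#' @param sr Sampling rate in Hz.
#' @param fft_size FFT length in samples.
#' @param n_mels Number of filters.
#' @return A `(fft_size/2 + 1) x n_mels` weight matrix.
#' @export
mel_filterbank <- function(sr, fft_size, n_mels) {
  n_bins <- fft_size / 2 + 1
  freqs <- (0:(n_bins - 1)) * sr / fft_size
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sr / 2), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_bins, n_mels)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Centre frequencies of the mel filter bank
#' @inheritParams mel_filterbank
#' @return Numeric vector of `n_mels` centre frequencies in Hz.
#' @export
mel_centers <- function(sr, n_mels) {
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sr / 2), length.out = n_mels + 2)
  mel_to_hz(mel_pts)[2:(n_mels + 1)]
}

frame_power_spectrum <- function(frames, fft_size) {
  fl <- ncol(frames)
  if (fft_size < fl) {
    stop("fft_size (", fft_size, ") is smaller than the frame length (",
         fl, ")", call. = FALSE)
  }
  padded <- matrix(0, fft_size, nrow(frames))
  padded[seq_len(fl), ] <- t(frames)
  spec <- stats::mvfft(padded)[seq_len(fft_size / 2 + 1), , drop = FALSE]
  t(abs(spec)^2)                      # n_frames x n_bins
}

new_feature_matrix <- function(values, feature, sample_rate, meta = list()) {
  structure(
    list(values = values, feature = feature, sample_rate = sample_rate,
         tl = nrow(values), meta = meta),
    class = "bs_features"
  )
}

#' @export
print.bs_features <- function(x, ...) {
  cat(sprintf("<bs_features %s: %d frames x %d coefficients @ %g Hz>\n",
              x$feature, nrow(x$values), ncol(x$values), x$sample_rate))
  invisible(x)
}

#' Log mel-spectrum of framed audio
#'
#' Per-frame power spectrum (zero-padded FFT, `|FFT|^2`), mapped through the
#' triangular mel filter bank, then `log(x + log_floor)`.
#'
#' @param frames A `bs_frames` object (already windowed if desired).
#' @param cfg A [feature_config()].
#' @param sr Sampling rate; defaults to the rate stored in `frames`.
#' @return A `bs_features` object, `n_frames x n_mels`.
#' @export
mel_spectrogram <- function(frames, cfg = feature_config("mel"), sr = NULL) {
  stopifnot(inherits(frames, "bs_frames"))
  sr <- sr %||% frames$sample_rate
  fft_size <- cfg$fft_size %||% next_pow2(frames$frame_length)
  pow <- frame_power_spectrum(frames$frames, fft_size)
  fb <- mel_filterbank(sr, fft_size, cfg$n_mels)
  vals <- log(pow %*% fb + cfg$log_floor)
  new_feature_matrix(vals, "mel", sr,
                     meta = list(fl = frames$frame_length,
                                 fs = frames$frame_shift,
                                 window = frames$window,
                                 fft_size = fft_size, n_mels = cfg$n_mels))
}

#' Orthonormal DCT-II matrix
#'
#' `D[k+1, n+1] = s_k sqrt(2/N) cos(pi (2n + 1) k / (2N))` with
#' `s_0 = 1/sqrt(2)`, so that `D %*% t(D)` is the identity.
#'
#' @param n Transform size.
#' @return An `n x n` orthonormal matrix.
#' @export
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Mel-frequency cepstral coefficients
#'
#' The orthonormal DCT-II of each frame's log-mel vector, keeping the first
#' `n_mfcc` coefficients (coefficient 0, the overall log energy across the
#' filter bank, is included).
#'
#' @inheritParams mel_spectrogram
#' @return A `bs_features` object, `n_frames x n_mfcc`.
#' @export
mfcc <- function(frames, cfg = feature_config("mfcc"), sr = NULL) {
  if (cfg$n_mfcc > cfg$n_mels) {
    stop("n_mfcc (", cfg$n_mfcc, ") exceeds n_mels (", cfg$n_mels, ")",
         call. = FALSE)
  }
  mel <- mel_spectrogram(frames, cfg, sr)
  D <- dct_matrix(cfg$n_mels)
  vals <- mel$values %*% t(D[seq_len(cfg$n_mfcc), , drop = FALSE])
  meta <- mel$meta
  meta$n_mfcc <- cfg$n_mfcc
  new_feature_matrix(vals, "mfcc", mel$sample_rate, meta)
}

#' Levinson-Durbin recursion
#'
#' Solves the Toeplitz normal equations of the autocorrelation method. Given
#' autocorrelations `r[1..order+1]` (lag 0 first), returns the predictor
#' coefficients `a` (sign convention `xhat[t] = sum_k a[k] x[t-k]`), the
#' reflection coefficients, and the final prediction-error power.
#'
#' @param r Autocorrelation sequence, lags 0..order.
#' @param order Predictor order.
#' @return List with `a`, `reflection`, `err`.
#' @export
levinson_durbin <- function(r, order) {
  stopifnot(length(r) >= order + 1)
  a <- numeric(order)
  k <- numeric(order)
  err <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[1:(i - 1)] * r[i:2])
    ki <- acc / err
    k[i] <- ki
    a_new <- a
    a_new[i] <- ki
    if (i > 1) a_new[1:(i - 1)] <- a[1:(i - 1)] - ki * a[(i - 1):1]
    a <- a_new
    err <- err * (1 - ki^2)
    if (err <= 0) break                 # numerically singular; stop early
  }
  list(a = a, reflection = k, err = err)
}

#' Linear predictive coding coefficients per frame
#'
#' Autocorrelation-method LPC solved by the Levinson-Durbin recursion. Each
#' output row holds the predictor coefficients `a[1..order]` with the sign
#' convention `xhat[t] = sum_k a[k] x[t-k]`. Zero-energy frames yield
#' all-zero coefficients so silent segments remain processable.
#'
#' @param frames A `bs_frames` object.
#' @param order Predictor order (must be `< fl`).
#' @return A `bs_features` object, `n_frames x order`.
#' @export
lpc <- function(frames, order = 12) {
  stopifnot(inherits(frames, "bs_frames"))
  fl <- frames$frame_length
  if (order >= fl) {
    stop("LPC order (", order, ") must be smaller than the frame length (",
         fl, ")", call. = FALSE)
  }
  X <- frames$frames
  out <- matrix(0, nrow(X), order)
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    r <- autocorr(x, order)
    if (r[1] <= .Machine$double.eps * fl) next
    out[i, ] <- levinson_durbin(r, order)$a
  }
  new_feature_matrix(out, "lpc", frames$sample_rate,
                     meta = list(fl = fl, fs = frames$frame_shift,
                                 window = frames$window, order = order))
}

#' Biased autocorrelation at lags 0..max_lag
#' @param x Numeric vector.
#' @param max_lag Largest lag.
#' @return Numeric vector of length `max_lag + 1`.
#' @export
autocorr <- function(x, max_lag) {
  n <- length(x)
  vapply(0:max_lag, function(l) sum(x[1:(n - l)] * x[(1 + l):n]), numeric(1))
}

#' Regularise a feature matrix to a fixed number of frames
#'
#' Truncates trailing frames when the matrix is too long and zero-pads
#' trailing frames when it is too short, so every segment presents exactly
#' `tl` time steps to the models.
#'
#' @param fm A `bs_features` object.
#' @param tl Target number of frames (`>= 1`).
#' @return A `bs_features` object with `tl` rows.
#' @export
fit_feature_length <- function(fm, tl) {
  stopifnot(inherits(fm, "bs_features"), tl >= 1)
  n <- nrow(fm$values)
  if (n > tl) {
    fm$values <- fm$values[seq_len(tl), , drop = FALSE]
  } else if (n < tl) {
    fm$values <- rbind(fm$values,
                       matrix(0, tl - n, ncol(fm$values)))
  }
  fm$tl <- tl
  fm$meta$tl <- tl
  fm
}

#' Full feature-extraction pipeline for one segment
#'
#' Frames the (already normalised / pre-emphasised) clip, applies the
#' window, extracts the requested feature family, and regularises to `tl`
#' frames.
#'
#' @param clip A [bs_clip].
#' @param feature `"mel"`, `"mfcc"` or `"lpc"`.
#' @param fl,fs Frame length and shift in samples.
#' @param tl Target feature length in frames.
#' @param window Window name.
#' @param cfg Optional [feature_config()]; defaults to one for `feature`.
#' @return A `bs_features` object, `tl x n_coeffs`.
#' @export
extract_features <- function(clip, feature = "mel", fl = 1024, fs = 441,
                             tl = 164, window = "hamming", cfg = NULL) {
  cfg <- cfg %||% feature_config(feature)
  fr <- apply_window(frame_signal(clip, fl, fs), window)
  fm <- switch(feature,
    mel  = mel_spectrogram(fr, cfg),
    mfcc = mfcc(fr, cfg),
    lpc  = lpc(fr, cfg$lpc_order),
    stop("unknown feature: ", feature, call. = FALSE)
  )
  fit_feature_length(fm, tl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
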