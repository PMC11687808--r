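test_that("mel filter bank covers the band with nonnegative weights", {
  fb <- mel_filterbank(44100, 1024, 40)
  expect_true(all(fb >= 0))
  centers <- mel_centers(44100, 40)
  freqs <- (0:(512)) * 44100 / 1024
  inside <- freqs > centers[1] & freqs < centers[40]
  expect_true(all(rowSums(fb)[inside] > 0))
})

test_that("mel spectrogram localises tones and scales as log power", {
  sr <- 44100
  tone <- bs_clip(sin(2 * pi * 1000 * (0:(sr / 2 - 1)) / sr), sr)
  fr <- apply_window(frame_signal(tone, 1024, 441), "hanning")
  cfg <- feature_config("mel", n_mels = 40)
  m <- mel_spectrogram(fr, cfg)
  centers <- mel_centers(sr, 40)
  nearest <- which.min(abs(centers - 1000))
  expect_true(all(apply(m$values, 1, which.max) == nearest))

  zeros <- frame_signal(numeric(2048), 512, 256, sample_rate = sr)
  mz <- mel_spectrogram(zeros, cfg)
  expect_true(all(mz$values == log(cfg$log_floor)))

  # doubling the amplitude adds log 4 to every well-excited log-power entry
  tone2 <- bs_clip(2 * tone$samples, sr)
  fr2 <- apply_window(frame_signal(tone2, 1024, 441), "hanning")
  m2 <- mel_spectrogram(fr2, cfg)
  # entries far enough above the floor that the +log_floor bias is < 1e-6
  big <- m$values > 0
  expect_lt(max(abs((m2$values - m$values)[big] - log(4))), 1e-6)

  expect_error(
    mel_spectrogram(fr, feature_config("mel", fft_size = 512)),
    "smaller than the frame length")
})

test_that("the DCT is orthonormal and MFCC matches the direct-sum oracle", {
  D <- dct_matrix(40)
  expect_lt(max(abs(D %*% t(D) - diag(40))), 1e-10)
  # DCT of a constant vector: coefficient 0 is c * sqrt(N), the rest 0
  cvec <- rep(2.5, 16)
  dc <- dct_matrix(16) %*% cvec
  expect_equal(dc[1], 2.5 * sqrt(16))
  expect_lt(max(abs(dc[-1])), 1e-12)

  withr::local_seed(7)
  v <- rnorm(24)
  expect_lt(max(abs(dct_matrix(24) %*% v - naive_dct(v))), 1e-8)

  # full-size MFCC inverts back to the log-mel values
  clip <- bs_clip(rnorm(8000), 8000)
  fr <- apply_window(frame_signal(clip, 256, 128), "hamming")
  cfg_full <- feature_config("mfcc", n_mels = 20, n_mfcc = 20)
  mf <- mfcc(fr, cfg_full)
  ml <- mel_spectrogram(fr, cfg_full)
  rec <- mf$values %*% dct_matrix(20)
  expect_lt(max(abs(rec - ml$values)), 1e-8)

  expect_error(mfcc(fr, feature_config("mel", n_mels = 10, n_mfcc = 13)))
})

test_that("LPC recovers AR coefficients and matches a Toeplitz solve", {
  withr::local_seed(8)
  # AR(1): x[t] = 0.9 x[t-1] + e
  n <- 4096
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  fr <- frame_signal(x, n, n, sample_rate = 1000)
  a <- lpc(fr, order = 1)
  expect_lt(abs(a$values[1, 1] - 0.9), 0.05)

  # white noise: all coefficients near zero
  w <- frame_signal(rnorm(4096), 4096, 4096, sample_rate = 1000)
  aw <- lpc(w, order = 8)
  expect_true(all(abs(aw$values) < 0.1))

  # Levinson-Durbin equals the direct Toeplitz solve
  for (i in 1:5) {
    xx <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 512))
    r <- autocorr(xx, 8)
    expect_lt(max(abs(levinson_durbin(r, 8)$a - toeplitz_lpc(r, 8))), 1e-6)
    expect_true(all(abs(levinson_durbin(r, 8)$reflection) <= 1 + 1e-12))
  }

  # zero-energy frames yield zero coefficients, not an error
  z <- frame_signal(numeric(256), 128, 64, sample_rate = 1000)
  expect_true(all(lpc(z, 4)$values == 0))
  expect_error(lpc(z, 128), "smaller than the frame length")
})

test_that("feature length regularisation truncates and zero-pads", {
  withr::local_seed(9)
  fm <- bsr:::new_feature_matrix(matrix(rnorm(198 * 40), 198), "mel", 44100)
  short <- fit_feature_length(fm, 131)
  expect_equal(dim(short$values), c(131, 40))
  expect_equal(short$values, fm$values[1:131, ])
  fm2 <- bsr:::new_feature_matrix(matrix(rnorm(131 * 40), 131), "mel", 44100)
  long <- fit_feature_length(fm2, 164)
  expect_equal(dim(long$values), c(164, 40))
  expect_true(all(long$values[132:164, ] == 0))
  same <- fit_feature_length(fm2, 131)
  expect_identical(same$values, fm2$values)
})

test_that("all extractors return finite values on random audio", {
  withr::local_seed(10)
  clip <- bs_clip(runif(16000, -1, 1), 8000)
  for (feat in c("mel", "mfcc", "lpc")) {
    f <- extract_features(clip, feat, fl = 256, fs = 128, tl = 64)
    expect_true(all(is.finite(f$values)), info = feat)
    expect_equal(nrow(f$values), 64)
  }
})
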