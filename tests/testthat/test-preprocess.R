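test_that("WAV files round-trip through write and read at both depths", {
  withr::local_seed(1)
  x <- runif(4410, -0.95, 0.95)
  clip <- bs_clip(x, 44100, "rt")
  p24 <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, p24, bit_depth = 24)
  back <- read_wav(p24)
  expect_equal(back$sample_rate, 44100)
  expect_lte(max(abs(back$samples - x)), 2^-23)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, p16, bit_depth = 16)
  expect_lte(max(abs(read_wav(p16)$samples - x)), 2^-15)
  # duration contract: 2 s at 44.1 kHz is 88200 samples
  clip2 <- bs_clip(numeric(88200), 44100)
  pp <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip2, pp)
  expect_length(read_wav(pp)$samples, 88200)
})

test_that("stereo input is averaged to mono and errors are raised cleanly", {
  withr::local_seed(2)
  x <- runif(800, -0.5, 0.5)
  p <- withr::local_tempfile(fileext = ".wav")
  write_stereo_wav(x, -x, 8000, p)
  clip <- read_wav(p)
  expect_lte(max(abs(clip$samples)), 2^-15)   # channels cancel
  expect_error(read_wav(file.path(tempdir(), "no-such.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeLines("definitely not audio", bad)
  expect_error(read_wav(bad), "RIFF")
})

test_that("label CSVs are parsed, validated, and empty files allowed", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end,fmin,fmax", "0.10,0.35,120,800",
               "1.20,1.45,100,600"), p)
  lab <- read_labels(p)
  expect_equal(nrow(lab), 2)
  expect_equal(lab$start, c(0.10, 1.20))
  expect_equal(lab$f_max, c(800, 600))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("start,end,fmin,fmax", empty)
  expect_equal(nrow(read_labels(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end,fmin,fmax", "0.5,0.2,100,200"), bad)
  expect_error(read_labels(bad), "line 2")

  remap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t0,t1,lo,hi", "0.1,0.2,50,100"), remap)
  lab2 <- read_labels(remap, col_map = c(start = "t0", end = "t1",
                                         fmin = "lo", fmax = "hi"))
  expect_equal(lab2$end, 0.2)
})

test_that("peak normalisation maps every nonzero clip onto [-1, 1]", {
  expect_equal(peak_normalize(bs_clip(c(0.5, -0.25), 100))$samples,
               c(1, -0.5))
  z <- peak_normalize(bs_clip(c(0, 0, 0), 100))
  expect_equal(z$samples, c(0, 0, 0))
  withr::local_seed(3)
  for (i in 1:100) {
    x <- rnorm(50, sd = runif(1, 0.01, 10))
    out <- peak_normalize(bs_clip(x, 100))$samples
    expect_equal(max(abs(out)), 1)
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("pre-emphasis follows the first-order recurrence and inverts", {
  clip <- bs_clip(c(1, 1, 1), 100)
  expect_equal(pre_emphasize(clip, 0.97)$samples, c(1, 0.03, 0.03))
  expect_error(pre_emphasize(clip, 1), "alpha")
  expect_equal(pre_emphasize(clip, 0)$samples, clip$samples)
  expect_equal(pre_emphasize(bs_clip(c(1, 0, 0), 100), 0.5)$samples,
               c(1, -0.5, 0))
  # invertibility: x[t] = y[t] + alpha x[t-1]
  withr::local_seed(4)
  x <- rnorm(200)
  y <- pre_emphasize(bs_clip(x, 100), 0.97)$samples
  xr <- numeric(200)
  xr[1] <- y[1]
  for (t in 2:200) xr[t] <- y[t] + 0.97 * xr[t - 1]
  expect_lt(max(abs(xr - x)), 1e-10)
})

test_that("resampling preserves duration, identity, and tone frequency", {
  withr::local_seed(5)
  clip <- bs_clip(rnorm(88200), 44100)
  down <- resample_clip(clip, 8000)
  expect_length(down$samples, 16000)
  expect_equal(down$sample_rate, 8000)
  expect_identical(resample_clip(clip, 44100)$samples, clip$samples)
  tone <- bs_clip(sin(2 * pi * 100 * (0:88199) / 44100), 44100)
  half <- resample_clip(tone, 22050)
  spec <- abs(stats::fft(half$samples))[1:(length(half$samples) / 2)]
  f_peak <- (which.max(spec) - 1) * 22050 / length(half$samples)
  expect_lt(abs(f_peak - 100), 22050 / length(half$samples) + 1e-9)
})

test_that("frame counts match the sliding-window oracle on a random grid", {
  withr::local_seed(6)
  for (i in 1:40) {
    fl <- sample(8:600, 1)
    fs <- sample(1:400, 1)
    L <- fl + sample(0:5000, 1)
    fr <- frame_signal(rnorm(L), fl, fs, sample_rate = 1000)
    expect_equal(nrow(fr$frames), count_frames_loop(L, fl, fs))
    expect_equal(ncol(fr$frames), fl)
  }
  # the standard grid points used in the sweeps
  expect_equal(nrow(frame_signal(numeric(88200), 1024, 441,
                                 sample_rate = 44100)$frames), 198)
  expect_equal(nrow(frame_signal(numeric(88200), 1764, 661,
                                 sample_rate = 44100)$frames), 131)
  expect_equal(nrow(frame_signal(numeric(64), 64, 7,
                                 sample_rate = 100)$frames), 1)
  expect_error(frame_signal(numeric(10), 20, 5, sample_rate = 100),
               "exceeds")
  # frame i covers samples [i*fs, i*fs + fl)
  x <- seq_len(100)
  fr <- frame_signal(x, 10, 3, sample_rate = 100)
  expect_equal(fr$frames[1, ], 1:10)
  expect_equal(fr$frames[2, ], 4:13)
})

test_that("window functions match their closed forms", {
  fr <- frame_signal(rep(1, 12), 3, 3, sample_rate = 10)
  rect <- apply_window(fr, "rectangle")
  expect_identical(rect$frames, fr$frames)
  ham <- apply_window(fr, "hamming")
  expect_equal(ham$frames[1, ], c(0.08, 1, 0.08))
  han <- apply_window(fr, "hanning")
  expect_equal(han$frames[1, ], c(0, 1, 0))
  n <- 64
  w <- window_vector("hamming", n)
  expect_equal(w, 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_error(apply_window(fr, "kaiser"), "unknown window")
})

test_that("segments receive overlap-based labels deterministically", {
  sr <- 1000
  lab1 <- tibble::tibble(start = 0.5, end = 1.0, f_min = 100, f_max = 500)
  clip2 <- bs_clip(numeric(2 * sr), sr)
  segs <- segment_and_label(clip2, lab1, seg_len = 2)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$label, 1L)

  segs0 <- segment_and_label(clip2, lab1[0, ], seg_len = 2)
  expect_equal(segs0[[1]]$label, 0L)

  clip4 <- bs_clip(numeric(4 * sr), sr)
  lab2 <- tibble::tibble(start = 2.5, end = 2.8, f_min = 100, f_max = 500)
  segs2 <- segment_and_label(clip4, lab2, seg_len = 2, hop = 2)
  expect_equal(vapply(segs2, `[[`, integer(1), "label"), c(0L, 1L))
  expect_equal(vapply(segs2, function(s) length(s$clip$samples),
                      integer(1)), c(2000L, 2000L))

  expect_error(segment_and_label(clip2, lab1, seg_len = 5), "exceeds")
  # determinism
  a <- segment_and_label(clip4, lab2, seg_len = 2, hop = 0.5)
  b <- segment_and_label(clip4, lab2, seg_len = 2, hop = 0.5)
  expect_identical(lapply(a, `[[`, "label"), lapply(b, `[[`, "label"))
  expect_identical(a[[3]]$clip$samples, b[[3]]$clip$samples)
  # partial overlap below the threshold share of the event stays negative
  lab3 <- tibble::tibble(start = 1.9, end = 2.9, f_min = 1, f_max = 2)
  segs3 <- segment_and_label(clip4, lab3, seg_len = 2, hop = 2,
                             overlap_threshold = 0.5)
  expect_equal(segs3[[1]]$label, 0L)   # only 0.1 s of a 1 s event
  expect_equal(segs3[[2]]$label, 1L)   # 0.9 s of it
})
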