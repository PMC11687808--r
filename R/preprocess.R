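#' Construct an audio clip
#'
#' The basic container for a mono waveform: an amplitude vector, its sampling
#' rate in Hz, and an opaque identifier recording where it came from.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Sampling rate in Hz.
#' @param source_id Optional identifier (defaults to `"clip"`).
#' @return An object of class `bs_clip`.
#' @export
bs_clip <- function(samples, sample_rate, source_id = "clip") {
  stopifnot(is.numeric(samples), length(sample_rate) == 1, sample_rate > 0)
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id)),
    class = "bs_clip"
  )
}

#' @export
print.bs_clip <- function(x, ...) {
  cat(sprintf("<bs_clip '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip A [bs_clip].
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Read a CSV file of bowel-sound event annotations
#'
#' Each annotated event has a start and end time in seconds and the lowest
#' and highest frequency (Hz) observed in the event. Column names are
#' configurable because annotation tools differ; the default mapping expects
#' `start`, `end`, `fmin`, `fmax`.
#'
#' @param path Path to the CSV file (must have a header row).
#' @param col_map Named character vector mapping the canonical fields
#'   `start`, `end`, `fmin`, `fmax` to the column names used in the file.
#' @return A tibble with columns `start`, `end`, `f_min`, `f_max`, one row
#'   per event. Times in seconds, frequencies in Hz.
#' @export
read_labels <- function(path,
                        col_map = c(start = "start", end = "end",
                                    fmin = "fmin", fmax = "fmax")) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- unname(col_map[c("start", "end", "fmin", "fmax")])
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("label file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    start = as.numeric(df[[col_map[["start"]]]]),
    end   = as.numeric(df[[col_map[["end"]]]]),
    f_min = as.numeric(df[[col_map[["fmin"]]]]),
    f_max = as.numeric(df[[col_map[["fmax"]]]])
  )
  if (nrow(out) == 0) return(out)
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    # header is line 1, so data row i is file line i + 1
    if (anyNA(r)) {
      stop("malformed label row at line ", i + 1, " of ", path,
           ": non-numeric field", call. = FALSE)
    }
    if (r$start < 0 || r$end <= r$start) {
      stop("malformed label row at line ", i + 1, " of ", path,
           ": need 0 <= start < end", call. = FALSE)
    }
    if (r$f_min > r$f_max) {
      stop("malformed label row at line ", i + 1, " of ", path,
           ": f_min > f_max", call. = FALSE)
    }
  }
  out
}

#' Peak-normalise a clip to [-1, 1]
#'
#' Divides by the maximum absolute amplitude so that every nonzero clip has
#' peak 1. This removes between-recording volume differences before feature
#' extraction. An all-zero clip is returned unchanged.
#'
#' @param clip A [bs_clip].
#' @return A [bs_clip] with `max(abs(samples)) == 1` (or all zeros).
#' @export
peak_normalize <- function(clip) {
  stopifnot(inherits(clip, "bs_clip"))
  peak <- max(abs(clip$samples))
  if (peak > 0) clip$samples <- clip$samples / peak
  clip
}

#' Apply first-order pre-emphasis
#'
#' `y[t] = x[t] - alpha * x[t-1]`, with `y[1] = x[1]`. Boosts the high
#' frequencies where short transient events carry most of their energy.
#'
#' @param clip A [bs_clip].
#' @param alpha Pre-emphasis coefficient in `[0, 1)`; 0.97 is the usual
#'   speech-processing default.
#' @return A filtered [bs_clip].
#' @export
pre_emphasize <- function(clip, alpha = 0.97) {
  stopifnot(inherits(clip, "bs_clip"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    stop("alpha must lie in [0, 1)", call. = FALSE)
  }
  x <- clip$samples
  if (length(x) > 1) {
    clip$samples <- c(x[1], x[-1] - alpha * x[-length(x)])
  }
  clip
}

#' Resample a clip to a new sampling rate
#'
#' Band-limited polyphase resampling (via [signal::resample()]). The output
#' length is `round(L * target_sr / sr)`; resampling to the current rate is
#' the identity.
#'
#' @param clip A [bs_clip].
#' @param target_sr Target sampling rate in Hz.
#' @return A [bs_clip] at `target_sr`.
#' @export
resample_clip <- function(clip, target_sr) {
  stopifnot(inherits(clip, "bs_clip"), target_sr > 0)
  sr <- clip$sample_rate
  if (target_sr == sr) return(clip)
  g <- gcd_int(round(target_sr), round(sr))
  p <- round(target_sr) / g
  q <- round(sr) / g
  y <- signal::resample(clip$samples, p, q)
  n_out <- round(length(clip$samples) * target_sr / sr)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  bs_clip(y, target_sr, source_id = clip$source_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Cut a clip into fixed-length segments and label them
#'
#' Slides a window of `seg_len` seconds with stride `hop` over the clip and
#' assigns each window a binary label from the event annotations: a segment
#' is positive (label 1) when its summed overlap with the annotated events
#' reaches `overlap_threshold` times the shortest event it touches. Windows
#' use half-open intervals `[start, end)`.
#'
#' @param clip A [bs_clip].
#' @param labels Tibble of events as returned by [read_labels()] (may have
#'   zero rows).
#' @param seg_len Segment duration in seconds (default 2, the clip length
#'   used in contact-microphone bowel-sound corpora).
#' @param hop Stride between segment starts in seconds (default `seg_len`,
#'   i.e. non-overlapping segments).
#' @param overlap_threshold Fraction in `(0, 1]` of the shortest involved
#'   event duration that must be covered for a positive label.
#' @return A list of `bs_segment` objects, each with fields `clip`, `label`
#'   (0/1) and `start_time`.
#' @export
segment_and_label <- function(clip, labels, seg_len = 2, hop = seg_len,
                              overlap_threshold = 0.5) {
  stopifnot(inherits(clip, "bs_clip"))
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    stop("overlap_threshold must lie in (0, 1]", call. = FALSE)
  }
  dur <- clip_duration(clip)
  if (seg_len > dur + 1e-9) {
    stop("seg_len (", seg_len, " s) exceeds clip duration (", dur, " s)",
         call. = FALSE)
  }
  sr <- clip$sample_rate
  n_seg_samp <- round(seg_len * sr)
  n_windows <- 1 + floor((dur - seg_len) / hop + 1e-9)
  segs <- vector("list", n_windows)
  for (k in seq_len(n_windows)) {
    t0 <- (k - 1) * hop
    t1 <- t0 + seg_len
    i0 <- round(t0 * sr)
    samp <- clip$samples[(i0 + 1):min(i0 + n_seg_samp, length(clip$samples))]
    if (length(samp) < n_seg_samp) {
      samp <- c(samp, numeric(n_seg_samp - length(samp)))
    }
    label <- 0L
    if (!is.null(labels) && nrow(labels) > 0) {
      ov <- pmax(0, pmin(labels$end, t1) - pmax(labels$start, t0))
      involved <- ov > 0
      if (any(involved)) {
        shortest <- min(labels$end[involved] - labels$start[involved])
        if (sum(ov) >= overlap_threshold * shortest - 1e-12) label <- 1L
      }
    }
    segs[[k]] <- structure(
      list(clip = bs_clip(samp, sr,
                          source_id = sprintf("%s#%d", clip$source_id, k)),
           label = label,
           start_time = t0),
      class = "bs_segment"
    )
  }
  segs
}

#' @export
print.bs_segment <- function(x, ...) {
  cat(sprintf("<bs_segment '%s' @ %.2f s, label %d>\n",
              x$clip$source_id, x$start_time, x$label))
  invisible(x)
}

#' Slice a signal into overlapping analysis frames
#'
#' Frame `i` covers samples `[(i-1)*fs + 1, (i-1)*fs + fl]`; the number of
#' complete frames is `1 + floor((L - fl) / fs)`. There is no padding and no
#' centring: a trailing partial frame is dropped. Under this convention a
#' 2-second clip at 44.1 kHz framed with `fl = 1764`, `fs = 661` yields 131
#' frames, which is the shortest standard feature length used in the sweeps.
#'
#' @param clip A [bs_clip] or a numeric vector.
#' @param frame_length Frame length `fl` in samples.
#' @param frame_shift Frame shift (hop) `fs` in samples.
#' @param sample_rate Required if `clip` is a bare vector.
#' @return A `bs_frames` object: matrix `frames` (`n_frames` x `fl`) plus
#'   framing metadata.
#' @export
frame_signal <- function(clip, frame_length, frame_shift, sample_rate = NULL) {
  if (inherits(clip, "bs_clip")) {
    x <- clip$samples
    sample_rate <- clip$sample_rate
  } else {
    x <- as.numeric(clip)
    if (is.null(sample_rate)) {
      stop("sample_rate is required for a bare vector", call. = FALSE)
    }
  }
  fl <- as.integer(frame_length)
  fs <- as.integer(frame_shift)
  if (fs < 1) stop("frame_shift must be >= 1", call. = FALSE)
  L <- length(x)
  if (fl > L) {
    stop("frame_length (", fl, ") exceeds signal length (", L, ")",
         call. = FALSE)
  }
  n_frames <- 1 + (L - fl) %/% fs
  idx <- outer(seq_len(fl), (seq_len(n_frames) - 1L) * fs, `+`)
  frames <- t(matrix(x[idx], nrow = fl))
  structure(
    list(frames = frames, frame_length = fl, frame_shift = fs,
         window = "rectangle", sample_rate = sample_rate),
    class = "bs_frames"
  )
}

#' @export
print.bs_frames <- function(x, ...) {
  cat(sprintf("<bs_frames: %d frames x %d samples (fs = %d, window = %s)>\n",
              nrow(x$frames), x$frame_length, x$frame_shift, x$window))
  invisible(x)
}

#' Window vectors used for framing
#'
#' Symmetric Hamming (`0.54 - 0.46 cos(2 pi n / (N-1))`) and Hanning
#' (`0.5 - 0.5 cos(2 pi n / (N-1))`) windows, or the all-ones rectangle.
#'
#' @param window_name One of `"hanning"`, `"hamming"`, `"rectangle"`.
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
window_vector <- function(window_name, n) {
  switch(window_name,
    hanning   = as.numeric(signal::hanning(n)),
    hamming   = as.numeric(signal::hamming(n)),
    rectangle = rep(1, n),
    stop("unknown window: ", window_name,
         " (expected hanning, hamming or rectangle)", call. = FALSE)
  )
}

#' Apply a window function to framed audio
#'
#' Multiplies every frame pointwise by the named window; the rectangle
#' window leaves frames unchanged. Tapered windows reduce spectral leakage
#' at frame boundaries.
#'
#' @param frames A `bs_frames` object from [frame_signal()].
#' @param window_name One of `"hanning"`, `"hamming"`, `"rectangle"`.
#' @return A `bs_frames` object with windowed frames.
#' @export
apply_window <- function(frames, window_name = "hamming") {
  stopifnot(inherits(frames, "bs_frames"))
  w <- window_vector(window_name, frames$frame_length)
  frames$frames <- sweep(frames$frames, 2, w, `*`)
  frames$window <- window_name
  frames
}
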