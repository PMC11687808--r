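#' Configuration for the synthetic bowel-sound surrogate generator
#'
#' Generates 2-second mono clips in which short band-limited noise bursts
#' (bowel-sound surrogates: brief broadband clicks concentrated in the low
#' hundreds of Hz) sit on a white or pink background. Half of the clips
#' contain at least one burst; the other half are background only, giving a
#' balanced binary task whose difficulty is controlled by the
#' signal-to-noise ratio. The burst model makes no claim of physiological
#' realism; it reproduces the label schema (event times plus a frequency
#' band) and the separability structure of the task.
#'
#' @param n_clips Number of clips (`>= 1`).
#' @param sample_rate Sampling rate in Hz.
#' @param clip_len Clip duration in seconds.
#' @param event_rate Expected bursts per positive clip.
#' @param burst_dur_range Burst duration range in seconds.
#' @param burst_band Two-element frequency band (Hz) of the bursts; must
#'   lie inside `(0, sample_rate/2)`.
#' @param snr_db Burst-to-background RMS ratio in dB. The default, 10 dB,
#'   is hard enough that a constant classifier fails and easy enough that a
#'   small encoder separates the classes well.
#' @param background `"white"` or `"pink"`.
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A `bs_synth_config` list.
#' @export
synth_config <- function(n_clips = 10, sample_rate = 44100, clip_len = 2,
                         event_rate = 1.5, burst_dur_range = c(0.02, 0.2),
                         burst_band = c(100, 1000), snr_db = 10,
                         background = c("white", "pink"), seed = 1) {
  background <- match.arg(background)
  stopifnot(n_clips >= 1, burst_band[1] > 0,
            burst_band[2] < sample_rate / 2,
            burst_dur_range[2] < clip_len)
  structure(
    list(n_clips = n_clips, sample_rate = sample_rate, clip_len = clip_len,
         event_rate = event_rate, burst_dur_range = burst_dur_range,
         burst_band = burst_band, snr_db = snr_db, background = background,
         seed = seed),
    class = "bs_synth_config"
  )
}

#' Generate one band-limited noise burst
#'
#' White noise band-pass filtered to `burst_band` (4th-order Butterworth,
#' zero-phase) with an attack-decay amplitude envelope; the duration is
#' drawn uniformly from `burst_dur_range`. Draws from the current RNG
#' state, so identical states give identical snippets.
#'
#' @param cfg A [synth_config()].
#' @return Numeric waveform snippet with peak amplitude 1.
#' @export
generate_burst <- function(cfg) {
  sr <- cfg$sample_rate
  dur <- stats::runif(1, cfg$burst_dur_range[1], cfg$burst_dur_range[2])
  n <- max(16, round(dur * sr))
  bf <- signal::butter(4, cfg$burst_band / (sr / 2), type = "pass")
  # pad so the zero-phase filter start-up transient stays out of the burst
  pad <- min(2048, 4 * n)
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  t <- seq_len(n) / n
  attack <- pmin(1, t / 0.1)                 # 10% linear attack
  decay <- exp(-3 * pmax(0, t - 0.1))        # exponential decay
  x <- x * attack * decay
  x / max(abs(x))
}

pink_noise <- function(n) {
  # Kellet's 3-pole pink filter applied to white noise
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  as.numeric(signal::filter(b, a, stats::rnorm(n)))
}

#' Generate one synthetic clip with its ground-truth events
#'
#' @param cfg A [synth_config()].
#' @param positive Should the clip contain bursts?
#' @param source_id Identifier for the clip.
#' @return A list with `clip` (a [bs_clip], peak 0.9) and `events`
#'   (tibble `start`, `end`, `f_min`, `f_max`; zero rows when negative).
#' @export
synth_clip <- function(cfg, positive, source_id = "synth") {
  sr <- cfg$sample_rate
  n <- round(cfg$clip_len * sr)
  bg <- if (cfg$background == "pink") pink_noise(n) else stats::rnorm(n)
  bg_rms <- sqrt(mean(bg^2))
  x <- bg
  events <- tibble::tibble(start = numeric(0), end = numeric(0),
                           f_min = numeric(0), f_max = numeric(0))
  if (positive) {
    n_events <- max(1, stats::rpois(1, cfg$event_rate))
    gain <- bg_rms * 10^(cfg$snr_db / 20)
    for (k in seq_len(n_events)) {
      burst <- generate_burst(cfg)
      nb <- length(burst)
      burst <- burst / sqrt(mean(burst^2)) * gain
      i0 <- sample.int(n - nb, 1)
      x[i0:(i0 + nb - 1)] <- x[i0:(i0 + nb - 1)] + burst
      events <- rbind(events, tibble::tibble(
        start = (i0 - 1) / sr, end = (i0 - 1 + nb) / sr,
        f_min = cfg$burst_band[1], f_max = cfg$burst_band[2]
      ))
    }
  }
  x <- 0.9 * x / max(abs(x))
  list(clip = bs_clip(x, sr, source_id = source_id), events = events)
}

#' Generate a balanced set of labelled synthetic segments in memory
#'
#' The first `ceiling(n_clips / 2)` clips contain bursts (label 1), the
#' rest are background only (label 0); the order is then deterministic in
#' the returned list. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A list of `bs_segment` objects with attached ground-truth
#'   `events` tibbles.
#' @export
synthetic_segments <- function(cfg) {
  withr::local_seed(cfg$seed)
  n_pos <- ceiling(cfg$n_clips / 2)
  out <- vector("list", cfg$n_clips)
  for (i in seq_len(cfg$n_clips)) {
    positive <- i <= n_pos
    sc <- synth_clip(cfg, positive, source_id = sprintf("synth%04d", i))
    seg <- structure(
      list(clip = sc$clip, label = as.integer(positive), start_time = 0),
      class = "bs_segment"
    )
    attr(seg, "events") <- sc$events
    out[[i]] <- seg
  }
  out
}

#' Write a synthetic dataset as WAV + CSV fixtures
#'
#' Writes `n_clips` WAV files (16-bit PCM by default) and one CSV label
#' file per clip in the event schema (`start`, `end`, `fmin`, `fmax`), plus
#' returns a manifest recording ground truth. Regeneration with the same
#' seed produces byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param bit_depth 16 or 24.
#' @return A `bs_synth_manifest` tibble: `wav`, `csv`, `label`, `n_events`.
#' @export
generate_dataset <- function(cfg, out_dir, bit_depth = 16) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  segs <- synthetic_segments(cfg)
  rows <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    wav_path <- file.path(out_dir, sprintf("clip%04d.wav", i))
    csv_path <- file.path(out_dir, sprintf("clip%04d.csv", i))
    write_wav(seg$clip, wav_path, bit_depth = bit_depth)
    ev <- attr(seg, "events")
    utils::write.csv(
      data.frame(start = ev$start, end = ev$end,
                 fmin = ev$f_min, fmax = ev$f_max),
      csv_path, row.names = FALSE
    )
    rows[[i]] <- tibble::tibble(wav = wav_path, csv = csv_path,
                                label = seg$label, n_events = nrow(ev))
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("bs_synth_manifest", class(manifest))
  manifest
}
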