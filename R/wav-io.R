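#' Read a PCM WAV file as a mono audio clip
#'
#' Parses a RIFF/WAVE file (PCM, 16- or 24-bit integer, or 32-bit IEEE float)
#' and returns a [bs_clip] whose samples are floats in `[-1, 1]`.
#' Multi-channel recordings are averaged down to mono; bowel-sound
#' recordings are mono to begin with, so this is a graceful degradation
#' rather than a supported workflow.
#'
#' @param path Path to a `.wav` file.
#' @return A [bs_clip].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE, which wraps PCM
  if (!fmt$audio_format %in% c(1L, 3L, -2L, 65534L)) {
    stop("unsupported WAV encoding (need PCM or IEEE float): ", path,
         call. = FALSE)
  }

  x <- switch(as.character(fmt$bits),
    "16" = {
      v <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                   signed = TRUE, endian = "little")
      v / 32768
    },
    "24" = {
      b <- as.integer(data_raw)
      n <- length(b) %/% 3
      idx <- 3 * seq_len(n)
      v <- b[idx - 2] + 256 * b[idx - 1] + 65536 * b[idx]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3L) {
        readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                endian = "little")
      } else {
        v <- readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
                     endian = "little")
        v / 2147483648
      }
    },
    stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
  )

  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  x <- pmin(pmax(x, -1), 1)
  bs_clip(x, fmt$sample_rate, source_id = basename(path))
}

#' Write an audio clip to a PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantised to the requested integer
#' depth. Synthetic fixtures default to 16-bit; 24-bit matches the depth of
#' typical contact-microphone bowel-sound recordings and exercises the
#' 24-bit decode path.
#'
#' @param clip A [bs_clip].
#' @param path Output path.
#' @param bit_depth 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = 16) {
  stopifnot(inherits(clip, "bs_clip"), bit_depth %in% c(16, 24))
  x <- pmin(pmax(clip$samples, -1), 1)
  n <- length(x)
  bytes_per <- bit_depth / 8
  full <- 2^(bit_depth - 1)
  v <- pmin(pmax(round(x * full), -full), full - 1)

  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else {
    u <- ifelse(v < 0, v + 16777216, v)
    b <- integer(3 * n)
    b[seq(1, by = 3, length.out = n)] <- u %% 256
    b[seq(2, by = 3, length.out = n)] <- (u %/% 256) %% 256
    b[seq(3, by = 3, length.out = n)] <- (u %/% 65536) %% 256
    writeBin(as.raw(b), con)
  }
  if (data_size %% 2 == 1) writeBin(as.raw(0), con)
  invisible(path)
}
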