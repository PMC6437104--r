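#' Read a PCM WAV file into an audio record
#'
#' Parses a RIFF/WAVE container holding uncompressed integer PCM (8, 16, 24 or
#' 32 bit) or IEEE float samples. Stereo and multichannel input is downmixed to
#' mono by averaging channels; samples are rescaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param subject_id,class_label,laugh_id Optional metadata attached to the
#'   returned record.
#' @return An [audio_record()].
#' @export
read_wav <- function(path, subject_id = NA_character_, class_label = NA_character_,
                     laugh_id = NA_character_) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE stream: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (!fmt$audio_format %in% c(1L, 3L)) {
    stop("unsupported WAV codec (format tag ", fmt$audio_format,
         "); only uncompressed PCM or IEEE float is supported")
  }

  if (fmt$audio_format == 3L) {
    x <- readBin(data_raw, "double", length(data_raw) / (fmt$bits / 8),
                 size = fmt$bits / 8, endian = "little")
  } else if (fmt$bits == 8L) {
    x <- (readBin(data_raw, "integer", length(data_raw), 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) / 3
    b <- matrix(as.integer(data_raw), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else if (fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 4, 4,
                 signed = TRUE, endian = "little") / 2^31
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }

  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_record(x, fmt$sample_rate, subject_id = subject_id,
               class_label = class_label, laugh_id = laugh_id)
}

#' Write an audio record as 16-bit PCM WAV
#'
#' @param record An [audio_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path) {
  stopifnot(inherits(record, "audio_record"))
  x <- pmax(pmin(record$samples, 1), -1)
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  fs <- as.integer(record$sample_rate_hz)
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")       # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct an audio record
#'
#' The unit consumed by every downstream stage: a mono waveform normalized to
#' `[-1, 1]` with its sample rate and optional subject/laugh metadata.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param subject_id,class_label,laugh_id Optional metadata.
#' @return An object of class `audio_record`.
#' @export
audio_record <- function(samples, sample_rate_hz, subject_id = NA_character_,
                         class_label = NA_character_, laugh_id = NA_character_) {
  if (length(samples) == 0) stop("audio record must be non-empty")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (max(abs(samples)) > 1 + 1e-9) stop("samples must lie in [-1, 1]")
  structure(
    list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz,
         subject_id = subject_id, class_label = class_label, laugh_id = laugh_id),
    class = "audio_record"
  )
}

#' @export
print.audio_record <- function(x, ...) {
  cat(sprintf("<audio_record> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  if (!is.na(x$laugh_id)) cat("  laugh:", x$laugh_id)
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id)
  cat("\n")
  invisible(x)
}

#' Duration of an audio record in seconds
#' @param record An [audio_record()].
#' @export
audio_duration <- function(record) length(record$samples) / record$sample_rate_hz
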