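#' Audio recording container
#'
#' A mono waveform with sampling metadata. Samples are amplitudes in
#' \eqn{[-1, 1]}; `bit_depth` is provenance only (the waveform itself is
#' stored as double precision).
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param subject_id Optional subject identifier.
#' @param bit_depth Source bit depth (provenance only).
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate_hz, subject_id = "",
                            bit_depth = 16L) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio_recording: samples must be non-empty")
  if (any(!is.finite(samples))) stop("audio_recording: samples must be finite")
  if (max(abs(samples)) > 1 + 1e-9)
    stop("audio_recording: samples must lie in [-1, 1]")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (sample_rate_hz <= 0L) stop("audio_recording: sample_rate_hz must be positive")
  structure(
    list(samples = pmin(pmax(samples, -1), 1),
         sample_rate_hz = sample_rate_hz,
         subject_id = as.character(subject_id),
         bit_depth = as.integer(bit_depth)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %s: %.3f s @ %d Hz (%d-bit source)\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, x$bit_depth))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `audio_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$sample_rate_hz

#' Read a mono WAV file
#'
#' Supports uncompressed mono PCM at 16 or 24 bits and 32-bit IEEE float.
#'
#' @param path Path to a WAV file.
#' @param subject_id Subject identifier to attach (defaults to the file stem).
#' @return An `audio_recording`.
#' @export
read_wav <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("read_wav: missing fmt or data chunk")
  if (fmt$channels != 1L) stop("read_wav: only mono WAV is supported")
  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3L
      b <- matrix(as.integer(data_raw), nrow = 3L)
      v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3L) {
        readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
      } else stop("read_wav: 32-bit integer PCM not supported")
    },
    stop("read_wav: unsupported bit depth ", fmt$bits)
  )
  if (is.null(subject_id))
    subject_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  audio_recording(pmin(pmax(x, -1), 1), fmt$sample_rate, subject_id, fmt$bits)
}

#' Write a recording as mono 16-bit PCM WAV
#'
#' @param rec An `audio_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- as.integer(round(pmin(pmax(rec$samples, -1), 1) * 32767))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")   # PCM
  writeBin(1L, con, 2L, endian = "little")   # mono
  writeBin(rec$sample_rate_hz, con, 4L, endian = "little")
  writeBin(rec$sample_rate_hz * 2L, con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(x, con, 2L, endian = "little")
  invisible(path)
}
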