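# Minimal RIFF/WAVE I/O for mono recordings: PCM 16/24-bit and IEEE
# float32. Written by hand since no WAV reader ships with the
# environment's R packages; deliberately strict (mono only).

#' Read a mono WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float 32-bit mono files.
#' Stereo or other channel counts are rejected with a clear error.
#' Samples are returned normalized to `[-1, 1]` for PCM.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_envtacs("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_envtacs("not a RIFF/WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop_envtacs("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate = readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_envtacs("data chunk before fmt chunk")
      if (fmt$n_channels != 1L) {
        stop_envtacs(sprintf(
          "only mono WAV is supported (file has %d channels)", fmt$n_channels
        ))
      }
      n <- sz %/% (fmt$bits %/% 8)
      x <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
        readBin(con, "numeric", n, size = 4, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n, size = 2, endian = "little") / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
        raw3 <- readBin(con, "raw", 3L * n)
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop_envtacs(sprintf(
          "unsupported WAV encoding (format %d, %d bit)", fmt$audio_format, fmt$bits
        ))
      }
      return(waveform(x, fmt$rate))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
}

#' Write a waveform as a float32 mono WAV file
#'
#' @param wave A [waveform()] (or envelope / stimulation waveform).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "envt_waveform"))
  x <- wave$samples
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little") # IEEE float
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(round(wave$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(wave$rate)) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little") # block align
  writeBin(32L, con, size = 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}
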