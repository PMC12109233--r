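# Minimal RIFF/WAVE reader and writer (PCM 8/16/24/32-bit integer and
# 32/64-bit IEEE float), written against the format specification. Stereo
# (or any multi-channel) input is downmixed to mono by averaging, which is
# all the alignment features need.

#' Read a WAV audio file
#'
#' Supports uncompressed PCM (8, 16, 24, 32 bit) and IEEE float (32, 64
#' bit); multi-channel audio is downmixed to mono by channel averaging.
#'
#' @param path file path.
#' @return a list with `samples` (numeric in `[-1, 1]`) and `sample_rate`
#'   (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1L, 2L,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1L, 4L,
                              endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk")
      samples <- read_wav_data(con, size, fmt)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$n_channels > 1L) {
    m <- matrix(samples, nrow = fmt$n_channels)
    samples <- colMeans(m)
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}

read_wav_data <- function(con, size, fmt) {
  bytes <- fmt$bits %/% 8L
  n <- size %/% bytes
  if (fmt$audio_format == 3L) {        # IEEE float
    readBin(con, "double", n, bytes, endian = "little")
  } else if (fmt$audio_format == 1L) { # integer PCM
    if (fmt$bits == 8L) {
      (readBin(con, "integer", n, 1L, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(con, "integer", n, 2L, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      raw <- readBin(con, "raw", size)
      b <- matrix(as.integer(raw), nrow = 3L)
      v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(con, "integer", n, 4L, endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)
}

#' Write a mono WAV audio file (16-bit PCM)
#'
#' @param samples numeric vector in `[-1, 1]` (values are clamped).
#' @param sample_rate rate in Hz.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  s <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")      # PCM, mono
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")     # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
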