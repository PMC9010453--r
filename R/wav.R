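#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16- and 24-bit PCM and 32-bit float,
#' sufficient for calibrated stimulus export. PCM samples are expected in
#' `[-1, 1]` and are clipped if outside.
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel.
#' @param path Output path.
#' @param sample_rate Sampling rate, Hz.
#' @param format `"pcm16"`, `"pcm24"` or `"float32"`.
#' @return The path, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 200e3,
                      format = c("pcm16", "pcm24", "float32")) {
  format <- match.arg(format)
  x <- as.matrix(samples)
  n_ch <- ncol(x)
  n <- nrow(x)
  bits <- switch(format, pcm16 = 16L, pcm24 = 24L, float32 = 32L)
  bytes <- bits %/% 8L
  fmt_code <- if (format == "float32") 3L else 1L
  data_size <- n * n_ch * bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * bytes), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_ch * bytes), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  inter <- as.numeric(t(x))   # interleave channels
  if (format == "float32") {
    writeBin(inter, con, size = 4, endian = "little")
  } else if (format == "pcm16") {
    v <- as.integer(round(pmax(pmin(inter, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- round(pmax(pmin(inter, 1), -1) * 8388607)
    v[v < 0] <- v[v < 0] + 16777216   # two's complement, 24-bit
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Companion reader for [write_wav()]: PCM 16/24-bit and 32-bit float.
#' An optional sensitivity converts playback units to pascal:
#' `pressure = samples / sensitivity`.
#'
#' @param path WAV file path.
#' @param sensitivity Units per pascal, or `NULL` to return raw samples.
#' @return A list with `samples` (matrix, one column per channel),
#'   `sample_rate` and `bits`.
#' @export
read_wav <- function(path, sensitivity = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) {
    abort("not a RIFF/WAVE file", class = "quietscope_data_quality")
  }
  readBin(con, integer(), size = 4, endian = "little")
  readChar(con, 4)   # WAVE
  fmt_code <- n_ch <- sample_rate <- bits <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_ch <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      if (bits == 32 && fmt_code == 3) {
        data <- readBin(con, numeric(), n = sz / 4, size = 4,
                        endian = "little")
      } else if (bits == 16) {
        data <- readBin(con, integer(), n = sz / 2, size = 2,
                        endian = "little") / 32767
      } else if (bits == 24) {
        b <- as.integer(readBin(con, raw(), n = sz))
        v <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
          65536 * b[c(FALSE, FALSE, TRUE)]
        v[v >= 8388608] <- v[v >= 8388608] - 16777216
        data <- v / 8388607
      } else {
        abort("unsupported WAV encoding", class = "quietscope_data_quality")
      }
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  x <- matrix(data, ncol = n_ch, byrow = TRUE)
  if (!is.null(sensitivity)) x <- x / sensitivity
  list(samples = x, sample_rate = sample_rate, bits = bits)
}
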