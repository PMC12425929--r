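# Minimal RIFF/WAVE I/O for mono 16-bit PCM. The pipeline only ever touches
# this one flavour of WAV, so the reader is deliberately strict.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit signed integers.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param fs Sampling frequency in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  con <- tryCatch(file(path, "wb"),
    error = function(e) stop("write_wav: cannot open '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path File written by [write_wav()] or any mono PCM16 RIFF file.
#' @return A waveform: `list(samples = <numeric in [-1, 1]>, fs = <Hz>)`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("read_wav: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("read_wav: not a RIFF/WAVE file: ", path)
  }
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("read_wav: no data chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("read_wav: only mono PCM supported: ", path)
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      ba_bps <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (ba_bps[2] != 16L) stop("read_wav: only 16-bit PCM supported: ", path)
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (identical(id, "data")) {
      if (is.null(fs)) stop("read_wav: data chunk before fmt chunk in ", path)
      pcm <- readBin(con, "integer", n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(list(samples = pcm / 32767, fs = fs))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}
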