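#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer (no external audio dependency): 32-bit IEEE
#' float (format 3, default) or 16-bit PCM. Float mode stores the signal
#' as-is; PCM mode scales the maximum absolute value to full scale.
#'
#' @param x signal (numeric vector).
#' @param path output file.
#' @param fs sampling rate, Hz.
#' @param bits 32 (float) or 16 (PCM).
#' @return invisibly, `path`.
#' @export
write_wav <- function(x, path, fs = 44100, bits = 32) {
  stopifnot(bits %in% c(16, 32), all(is.finite(x)))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes <- bits / 8
  fmt <- if (bits == 32) 3L else 1L
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    sc <- max(abs(x), 1e-12)
    writeBin(as.integer(round(x / sc * 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Supports 16-bit PCM and 32-bit float mono files.
#'
#' @param path input file.
#' @return list with `x` (signal) and `fs` (sampling rate, Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, 2, endian = "little")
      nch <- readBin(con, "integer", 1, 2, endian = "little")
      if (nch != 1) stop("read_wav: only mono supported")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 2, endian = "little")
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      x <- if (fmt == 3 && bits == 32) {
        readBin(con, "numeric", sz / 4, 4, endian = "little")
      } else if (fmt == 1 && bits == 16) {
        readBin(con, "integer", sz / 2, 2, signed = TRUE,
                endian = "little") / 32767
      } else stop("read_wav: unsupported format ", fmt, "/", bits)
      return(list(x = x, fs = fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}
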