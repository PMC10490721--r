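# Minimal RIFF/WAVE (PCM 16-bit) reader and writer.
#
# Only canonical PCM chunks are supported: that is all the pipeline
# produces and consumes. Samples are exchanged as doubles in [-1, 1];
# multichannel data as a matrix with one column per channel.

#' Write a PCM 16-bit WAV file
#'
#' @param x numeric vector (mono) or matrix (samples x channels) with
#'   values in \[-1, 1\]; values outside are clipped.
#' @param path output file path.
#' @param rate sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate) {
  if (is.null(dim(x))) x <- matrix(as.double(x), ncol = 1L)
  n_ch <- ncol(x)
  n <- nrow(x)
  pcm <- as.integer(round(pmax(pmin(t(x), 1), -1) * 32767))
  data_bytes <- n * n_ch * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * n_ch * 2L, con, size = 4, endian = "little")
  writeBin(n_ch * 2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM 16-bit WAV file
#'
#' @param path file path.
#' @return list with `samples` (vector for mono, samples x channels matrix
#'   otherwise, doubles in \[-1, 1\]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  rate <- NULL
  n_ch <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path, call. = FALSE)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported", call. = FALSE)
      n_ch <- fmt[2]
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit WAV supported", call. = FALSE)
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2,
                     endian = "little", signed = TRUE)
      x <- matrix(pcm / 32767, nrow = n_ch)
      samples <- if (n_ch == 1L) drop(x) else t(x)
      return(list(samples = samples, rate = rate))
    } else {
      readBin(con, raw(), n = size + (size %% 2L))
    }
  }
}
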