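#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for PCM 16-bit, PCM 24-bit and IEEE-float
#' recordings.  Multi-channel input is reduced to the first channel with a
#' warning.  Amplitudes are returned scaled to \code{[-1, 1]}.
#'
#' @param path Path to a .wav file.
#' @return A [Waveform-class].
#' @seealso [writeWav()]
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sampleRate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bitsPerSample = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk in ", path)
  bits <- fmt$bitsPerSample
  if (fmt$audioFormat == 1L && bits == 16L) {
    x <- readBin(data, "integer", length(data) %/% 2L, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audioFormat == 1L && bits == 24L) {
    n <- length(data) %/% 3L
    b <- matrix(as.integer(data[seq_len(3L * n)]), nrow = 3L)
    x <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    x <- ifelse(x >= 8388608, x - 16777216, x) / 8388608
  } else if (fmt$audioFormat == 3L && bits == 32L) {
    x <- readBin(data, "numeric", length(data) %/% 4L, 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audioFormat, ", ",
         bits, " bit)")
  }
  if (fmt$nChannels > 1L) {
    warning("multi-channel recording: using the first channel only")
    x <- x[seq(1L, length(x), by = fmt$nChannels)]
  }
  waveform(pmax(-1, pmin(1, x)), fmt$sampleRate)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param w A [Waveform-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @seealso [readWav()]
#' @export
writeWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  x <- as.integer(round(pmax(-1, pmin(1, samples(w))) * 32767))
  dataSize <- 2L * length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")            # PCM, mono
  rate <- as.integer(round(rateHz(w)))
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4L, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, 2L, endian = "little")            # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4L, endian = "little")
  writeBin(x, con, 2L, endian = "little")
  invisible(path)
}
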