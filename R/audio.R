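#' Construct an audio signal
#'
#' The canonical container for audio throughout the package: a mono vector of
#' dimensionless amplitudes plus a sampling rate in Hz. Stereo input must be
#' mixed down before construction (see [read_wav()], which does so by channel
#' averaging).
#'
#' @param samples numeric vector of finite amplitudes (at least one sample)
#' @param sample_rate sampling rate in Hz (positive)
#' @param source_path optional path the audio came from
#' @return an object of class `audio_signal` with elements `samples`,
#'   `sample_rate` and `source_path`
#' @export
#' @examples
#' a <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration(a)
audio_signal <- function(samples, sample_rate, source_path = NULL) {
  if (!is.numeric(samples) || length(samples) < 1) {
    stop("'samples' must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("'sample_rate' must be a single positive number")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         source_path = source_path),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)%s>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$source_path)) "" else paste0(", ", x$source_path)))
  invisible(x)
}

#' @rdname audio_signal
#' @param x an `audio_signal`
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

# --- WAV (RIFF) reading and writing -----------------------------------------
# Minimal RIFF/WAVE support: PCM 16/24/32-bit and IEEE float 32/64-bit,
# mono or stereo. Chunks other than fmt/data are skipped.

#' Read a WAV file
#'
#' Reads RIFF/WAVE audio (integer PCM at 16/24/32 bits or IEEE float) into an
#' [audio_signal()]. Stereo files are mixed to mono by averaging the two
#' channels; integer PCM is rescaled to the nominal \[-1, 1\] range by dividing
#' by 2^(bits-1). The sample rate is preserved as stored: roughness estimated
#' as a proportion of the modulation spectrum is robust to sampling rate, so
#' no resampling or loudness normalization is applied.
#'
#' @param path path to a WAV file
#' @return an [audio_signal()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels  = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate      = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing fmt or data chunk): ", path)
  if (!fmt$channels %in% c(1L, 2L)) stop("only mono or stereo WAV supported: ", path)

  x <- decode_wav_samples(data_raw, fmt)
  if (length(x) == 0) stop("zero-length audio: ", path)
  if (fmt$channels == 2L) {
    n <- length(x) %/% 2L
    x <- (x[seq(1L, 2L * n, by = 2L)] + x[seq(2L, 2L * n, by = 2L)]) / 2
  }
  audio_signal(x, fmt$rate, source_path = path)
}

decode_wav_samples <- function(raw, fmt) {
  n_bytes <- fmt$bits %/% 8L
  n <- length(raw) %/% n_bytes
  if (fmt$format == 1L) {  # integer PCM
    if (fmt$bits == 16L) {
      readBin(raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(raw, "integer", n, 4, endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$format == 3L) {  # IEEE float
    if (fmt$bits == 32L) {
      readBin(raw, "double", n, 4, endian = "little")
    } else if (fmt$bits == 64L) {
      readBin(raw, "double", n, 8, endian = "little")
    } else stop("unsupported float bit depth: ", fmt$bits)
  } else stop("unsupported WAV format code: ", fmt$format)
}

#' Write an audio signal to a WAV file
#'
#' Writes 16-bit PCM (default) or 32-bit IEEE float mono WAV. Values outside
#' \[-1, 1\] are clipped for PCM output.
#'
#' @param x an [audio_signal()]
#' @param path output path
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float)
#' @return `path`, invisibly
#' @export
write_wav <- function(x, path, bit_depth = 16) {
  stopifnot(inherits(x, "audio_signal"), bit_depth %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x$samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(x$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(x$sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16) {
    v <- pmax(-1, pmin(1, x$samples))
    writeBin(as.integer(round(v * 32767)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x$samples), con, 4, endian = "little")
  }
  invisible(path)
}
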