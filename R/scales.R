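#' Psychoacoustic frequency scales and bandwidth rules
#'
#' Conversions between linear frequency (Hz) and the ERB-rate and bark scales,
#' plus the two bandwidth rules used by the auditory filterbank: the
#' Glasberg & Moore equivalent rectangular bandwidth (ERB) as a function of
#' center frequency, and a constant-Q bandwidth specified in semitones.
#'
#' The ERB-rate scale is \code{21.4 * log10(1 + 0.00437 * f)}; the bark scale
#' is \code{6 * asinh(f / 600)}. Both are strictly increasing and each has an
#' exact closed-form inverse.
#'
#' @param f frequency in Hz (non-negative, vectorized)
#' @param e ERB-rate value (non-negative)
#' @param z bark value (non-negative)
#' @param cf filter center frequency in Hz
#' @param s bandwidth in semitones (positive)
#' @return a numeric vector of the same length as the input
#' @examples
#' hz_to_erb(1000)          # ~15.62
#' erb_to_hz(hz_to_erb(440))
#' erb_bandwidth(1000)      # ~132.6 Hz
#' constant_q_bandwidth(1000, 12)  # 500 Hz at one octave
#' @name auditory_scales
NULL

#' @rdname auditory_scales
#' @export
hz_to_erb <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  if (any(f < 0)) stop("frequencies must be non-negative")
  21.4 * log10(1 + 0.00437 * f)
}

#' @rdname auditory_scales
#' @export
erb_to_hz <- function(e) {
  stopifnot(is.numeric(e), all(is.finite(e)))
  if (any(e < 0)) stop("ERB-rate values must be non-negative")
  (10^(e / 21.4) - 1) / 0.00437
}

#' @rdname auditory_scales
#' @export
hz_to_bark <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  if (any(f < 0)) stop("frequencies must be non-negative")
  6 * asinh(f / 600)
}

#' @rdname auditory_scales
#' @export
bark_to_hz <- function(z) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  if (any(z < 0)) stop("bark values must be non-negative")
  600 * sinh(z / 6)
}

#' @rdname auditory_scales
#' @export
erb_bandwidth <- function(cf) {
  stopifnot(is.numeric(cf), all(is.finite(cf)))
  if (any(cf < 0)) stop("center frequencies must be non-negative")
  24.7 * (4.37 * cf / 1000 + 1)
}

#' @rdname auditory_scales
#' @export
constant_q_bandwidth <- function(cf, s) {
  stopifnot(is.numeric(cf), is.numeric(s), all(is.finite(cf)), all(is.finite(s)))
  if (any(cf <= 0)) stop("center frequencies must be positive")
  if (any(s <= 0)) stop("semitone bandwidth must be positive")
  2 * cf * (2^(s / 12) - 1) / 2^(s / 12 + 1)
}
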