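#' Fragmentation settings
#'
#' Roughness is measured over short fragments rather than whole recordings:
#' `am_res` gives the number of measurements per second, so each fragment is
#' `1/am_res` seconds long. Around five fragments per second (200-ms
#' fragments) is a good compromise between precision and the ability to trace
#' roughness over time; accuracy only degrades once fragments shrink below
#' about 40 ms.
#'
#' @param am_res roughness measurements per second (> 0)
#' @param min_fragment_fraction a trailing remainder shorter than this
#'   fraction of a full fragment is merged into the previous fragment
#' @return an object of class `fragmentation_config`
#' @export
fragmentation_config <- function(am_res = 5, min_fragment_fraction = 0.5) {
  if (am_res <= 0) stop("am_res must be positive")
  if (min_fragment_fraction < 0 || min_fragment_fraction > 1) {
    stop("min_fragment_fraction must be in [0, 1]")
  }
  structure(list(am_res = am_res,
                 min_fragment_fraction = min_fragment_fraction),
            class = "fragmentation_config")
}

#' Split a time-frequency envelope into analysis fragments
#'
#' Cuts the envelope into contiguous, non-overlapping fragments of
#' `1/am_res` seconds. A trailing remainder shorter than
#' `min_fragment_fraction` of a full fragment is merged into the previous
#' fragment; an envelope shorter than one fragment is returned whole.
#'
#' @param env a [tf_envelope()]
#' @param config a [fragmentation_config()]
#' @return a list of [tf_envelope()] fragments, each carrying its start time
#'   (relative to the envelope start) in `t0`
#' @export
fragment <- function(env, config = fragmentation_config()) {
  stopifnot(inherits(env, "tf_envelope"))
  n <- ncol(env$values)
  frag_cols <- max(1L, round(1 / (config$am_res * env$time_step)))
  starts <- seq(1L, n, by = frag_cols)
  ends <- pmin(starts + frag_cols - 1L, n)
  n_frag <- length(starts)
  if (n_frag > 1) {
    last_len <- ends[n_frag] - starts[n_frag] + 1L
    if (last_len < config$min_fragment_fraction * frag_cols) {
      ends[n_frag - 1L] <- ends[n_frag]
      starts <- starts[-n_frag]
      ends <- ends[-n_frag]
      n_frag <- n_frag - 1L
    }
  }
  lapply(seq_len(n_frag), function(i) {
    tf_envelope(env$values[, starts[i]:ends[i], drop = FALSE],
                env$band_centers, env$time_step,
                t0 = (starts[i] - 1L) * env$time_step)
  })
}

mod_spectrum <- function(values, mod_freqs, band_centers, fragment_start,
                         fragment_rms) {
  structure(list(values = values, mod_freqs = mod_freqs,
                 band_centers = band_centers, fragment_start = fragment_start,
                 fragment_rms = fragment_rms),
            class = "mod_spectrum")
}

#' @export
print.mod_spectrum <- function(x, ...) {
  cat(sprintf("<mod_spectrum: %d bands x %d modulation bins (0-%g Hz), t = %.3f s>\n",
              nrow(x$values), ncol(x$values), max(x$mod_freqs),
              x$fragment_start))
  invisible(x)
}

#' Temporal modulation spectrum of one fragment (1D FFT per band)
#'
#' For each frequency band of the fragment, subtracts the band's mean over
#' the fragment, applies a Hann taper and an FFT, and keeps the magnitudes of
#' the non-negative-frequency bins raised to `exponent`. The taper matters:
#' a modulation rate that falls between the fragment's frequency bins would
#' otherwise leak energy across the entire modulation axis, and since that
#' axis extends much further for audio-rate envelopes than for STFT-band
#' envelopes, untapered spectra bias the normalized roughness of the two
#' pipelines differently. `taper = "none"` restores plain rectangular
#' fragments. Modulation bins are spaced `1/fragment_duration` Hz apart and
#' extend to the envelope Nyquist, `1/(2*time_step)`.
#'
#' @param frag a [tf_envelope()] fragment with at least 8 columns
#' @param exponent 1 (magnitude, the default and recommended setting) or 2
#'   (power)
#' @param taper `"hann"` (default) or `"none"`
#' @return a `mod_spectrum`: band x modulation-frequency matrix with
#'   `mod_freqs`, `band_centers`, `fragment_start` (s) and `fragment_rms`
#'   (RMS of the raw envelope values, used downstream for silence gating)
#' @export
mod_spectrum_1d <- function(frag, exponent = 1, taper = c("hann", "none")) {
  stopifnot(inherits(frag, "tf_envelope"))
  taper <- match.arg(taper)
  n <- ncol(frag$values)
  if (n < 8) stop("fragment too short for modulation analysis (< 8 columns)")
  w <- if (taper == "hann") stft_window("hann", n) else rep(1, n)
  n_keep <- floor(n / 2) + 1
  mags <- t(apply(frag$values, 1, function(row) {
    Mod(stats::fft((row - mean(row)) * w))[seq_len(n_keep)]
  }))^exponent
  mod_spectrum(matrix(mags, nrow = nrow(frag$values)),
               (seq_len(n_keep) - 1) / (n * frag$time_step),
               frag$band_centers, frag$t0,
               sqrt(mean(frag$values^2)))
}

#' Temporal modulation spectrum via 2D FFT (alternative route)
#'
#' Takes a 2D FFT of the fragment after removing each band's time-mean (this
#' zeroes the temporal-DC column, i.e. the static spectral profile, whose
#' leakage would otherwise dominate the low modulation frequencies exactly
#' as in the 1D route), folds the magnitude array
#' around zero temporal modulation frequency by averaging the negative- and
#' positive-frequency halves (for a real-valued spectrogram the two are
#' mirror images, so folding loses nothing), and collapses the
#' spectral-modulation axis by summation. The result is a single pooled
#' temporal-modulation profile in the same container as [mod_spectrum_1d()];
#' the per-band 1D route is the default as it performed better and keeps the
#' band axis interpretable.
#'
#' @inheritParams mod_spectrum_1d
#' @return a `mod_spectrum` with one pooled band
#' @export
mod_spectrum_2d <- function(frag, exponent = 1, taper = c("hann", "none")) {
  stopifnot(inherits(frag, "tf_envelope"))
  taper <- match.arg(taper)
  n <- ncol(frag$values)
  if (n < 8) stop("fragment too short for modulation analysis (< 8 columns)")
  m <- frag$values - rowMeans(frag$values)
  if (taper == "hann") m <- m * rep(stft_window("hann", n), each = nrow(m))
  M <- Mod(stats::fft(m))  # bands (spectral mod) x time (temporal mod)
  n_keep <- floor(n / 2) + 1
  pos <- M[, seq_len(n_keep), drop = FALSE]
  # fold: average each positive temporal frequency with its negative twin
  folded <- pos
  for (j in 2:n_keep) {
    jneg <- n - j + 2
    if (jneg > n_keep) folded[, j] <- (pos[, j] + M[, jneg]) / 2
  }
  pooled <- matrix(colSums(folded^exponent), nrow = 1)
  mod_spectrum(pooled, (seq_len(n_keep) - 1) / (n * frag$time_step),
               mean(frag$band_centers), frag$t0,
               sqrt(mean(frag$values^2)))
}

#' Average modulation spectra across fragments or recordings
#'
#' Cell-wise (weighted) arithmetic mean. Spectra whose modulation-frequency
#' grid differs from the first spectrum's are linearly interpolated onto it
#' per band (fragments of unequal length produce slightly different grids).
#' All spectra must share the same number of bands.
#'
#' @param spectra a non-empty list of `mod_spectrum` objects
#' @param weights optional non-negative per-spectrum weights (default uniform)
#' @return a `mod_spectrum` on the first spectrum's axes
#' @export
average_mod_spectra <- function(spectra, weights = NULL) {
  if (length(spectra) == 0) stop("empty list of spectra")
  stopifnot(all(vapply(spectra, inherits, logical(1), "mod_spectrum")))
  if (is.null(weights)) weights <- rep(1, length(spectra))
  if (length(weights) != length(spectra)) stop("one weight per spectrum required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("weights sum to zero")
  ref <- spectra[[1]]
  nb <- nrow(ref$values)
  acc <- matrix(0, nb, length(ref$mod_freqs))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (nrow(s$values) != nb) stop("spectra differ in number of bands")
    v <- if (length(s$mod_freqs) == length(ref$mod_freqs) &&
             all(abs(s$mod_freqs - ref$mod_freqs) < 1e-9)) {
      s$values
    } else {
      t(apply(s$values, 1, function(row) {
        stats::approx(s$mod_freqs, row, xout = ref$mod_freqs, rule = 2)$y
      }))
    }
    acc <- acc + weights[i] * v
  }
  mod_spectrum(acc / sum(weights), ref$mod_freqs, ref$band_centers,
               ref$fragment_start,
               sum(weights * vapply(spectra, `[[`, numeric(1), "fragment_rms")) /
                 sum(weights))
}
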