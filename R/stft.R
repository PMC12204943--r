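#' STFT configuration for modulation analysis
#'
#' Short windows and a very fine step are what make an ordinary spectrogram
#' usable for roughness: the band envelopes are sampled at `1000/step` Hz, so
#' their modulation Nyquist is `1000/(2*step)` — 250 Hz at the default 2-ms
#' step, covering the rough range. The defaults (25-ms window, 2-ms step,
#' Hann window, magnitude spectrogram) are the recommended configuration.
#'
#' @param window_length analysis window length in ms
#' @param step frame step in ms (0 < step <= window_length)
#' @param window_type `"hann"`, `"gaussian"`, `"hamming"` or `"bartlett"` —
#'   all perform near-identically for roughness
#' @param magnitude_exponent 1 (magnitude) or 2 (power)
#' @return an object of class `stft_config`
#' @export
stft_config <- function(window_length = 25, step = 2,
                        window_type = c("hann", "gaussian", "hamming",
                                        "bartlett"),
                        magnitude_exponent = 1) {
  window_type <- match.arg(window_type)
  if (step <= 0 || step > window_length) {
    stop("need 0 < step <= window_length")
  }
  if (!magnitude_exponent %in% c(1, 2)) stop("magnitude_exponent must be 1 or 2")
  structure(list(window_length = window_length, step = step,
                 window_type = window_type,
                 magnitude_exponent = magnitude_exponent),
            class = "stft_config")
}

stft_window <- function(type, n) {
  i <- seq_len(n) - 1
  switch(type,
    hann     = 0.5 - 0.5 * cos(2 * pi * i / (n - 1)),
    hamming  = 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
    bartlett = 1 - abs(2 * i / (n - 1) - 1),
    gaussian = exp(-0.5 * ((i - (n - 1) / 2) / (n / 6))^2)
  )
}

#' STFT magnitude spectrogram
#'
#' Frames start at the first sample and advance by `round(step * sr / 1000)`
#' samples; each frame is windowed and transformed with an FFT of exactly the
#' window length (no zero-padding), so the bin spacing is
#' `1000 / window_length` Hz. Values are magnitudes raised to
#' `magnitude_exponent` and are not log-transformed (log-transforming the
#' spectrogram is strongly detrimental for roughness estimation). A trailing
#' partial frame is dropped.
#'
#' @param signal an [audio_signal()]
#' @param config an [stft_config()]
#' @return a [tf_envelope()]: bins x frames, `band_centers` at the FFT bin
#'   frequencies, `time_step = step` (in seconds), columns stamped at frame
#'   centers
#' @export
stft <- function(signal, config = stft_config()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "stft_config"))
  sr <- signal$sample_rate
  wl <- round(config$window_length * sr / 1000)
  hop <- max(1L, round(config$step * sr / 1000))
  x <- signal$samples
  if (length(x) < wl) stop("signal shorter than one analysis window")
  n_frames <- floor((length(x) - wl) / hop) + 1
  win <- stft_window(config$window_type, wl)
  n_bins <- floor(wl / 2) + 1

  vals <- vapply(seq_len(n_frames), function(j) {
    fr <- x[seq((j - 1) * hop + 1, length.out = wl)] * win
    Mod(stats::fft(fr))[seq_len(n_bins)]^config$magnitude_exponent
  }, numeric(n_bins))
  tf_envelope(matrix(vals, nrow = n_bins), (seq_len(n_bins) - 1) * sr / wl,
              hop / sr, t0 = (wl / 2) / sr)
}

#' Check STFT settings against the constraints of roughness analysis
#'
#' Three constraints govern window/step choice when a spectrogram feeds
#' modulation analysis: (1) the step must sample band envelopes fast enough
#' to represent the fastest modulation of interest, so
#' `max_step = 1000 / mod_max / 2` ms; (2) the window must cover at least one
#' period of the lowest fundamental (else f0 itself masquerades as amplitude
#' modulation), so `min_window = 1000 / f0_min` ms; (3) modulation is masked
#' once the window spans more than about two periods of the modulation
#' frequency, giving a soft ceiling `2 * 1000 / mod_max` ms, with a hard
#' ceiling of `1000/30` ms from the widest useful band. The constraints
#' cannot all hold at once; violations are reported as warnings in the
#' returned report, never as errors.
#'
#' @param config an [stft_config()]
#' @param f0_min lowest fundamental frequency expected in the audio, Hz
#' @param mod_max fastest modulation frequency of interest, Hz
#' @return a list with `max_step`, `min_window`, `soft_max_window`,
#'   `hard_max_window` (all ms) and a character vector `warnings`
#' @export
validate_stft_settings <- function(config = stft_config(), f0_min = 100,
                                   mod_max = 250) {
  if (f0_min <= 0 || mod_max <= 0) stop("f0_min and mod_max must be positive")
  rep <- list(
    max_step        = 1000 / mod_max / 2,
    min_window      = 1000 / f0_min,
    soft_max_window = 2 * 1000 / mod_max,
    hard_max_window = 1000 / 30,
    warnings        = character()
  )
  w <- character()
  if (config$step > rep$max_step) {
    w <- c(w, sprintf("step %g ms exceeds %g ms: modulations up to %g Hz undersampled",
                      config$step, rep$max_step, mod_max))
  }
  if (config$window_length < rep$min_window) {
    w <- c(w, sprintf("window %g ms is shorter than one period of f0 = %g Hz (%g ms): f0 may register as amplitude modulation",
                      config$window_length, f0_min, rep$min_window))
  }
  if (config$window_length > rep$soft_max_window) {
    w <- c(w, sprintf("window %g ms spans more than ~2 periods of %g Hz modulation (soft limit %g ms): fast modulation attenuated",
                      config$window_length, mod_max, rep$soft_max_window))
  }
  if (config$window_length > rep$hard_max_window) {
    w <- c(w, sprintf("window %g ms gives bands narrower than the narrowest relevant critical band (limit %g ms)",
                      config$window_length, rep$hard_max_window))
  }
  rep$warnings <- w
  rep
}
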