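#' Time-frequency envelope container
#'
#' Common representation of both spectrogram types: a band x time matrix of
#' non-negative envelope or magnitude values, with band center frequencies in
#' Hz and a uniform column spacing in seconds. Auditory spectrograms keep
#' columns at the audio rate (`time_step = 1/sample_rate`); STFT spectrograms
#' at the frame step.
#'
#' @param values band x time numeric matrix, non-negative
#' @param band_centers band center frequencies in Hz, strictly ascending
#' @param time_step seconds between adjacent columns
#' @param t0 time of the first column, seconds
#' @return an object of class `tf_envelope`
#' @export
tf_envelope <- function(values, band_centers, time_step, t0 = 0) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("envelope values must be non-negative")
  if (nrow(values) != length(band_centers)) {
    stop("nrow(values) must equal length(band_centers)")
  }
  if (length(band_centers) > 1 && any(diff(band_centers) <= 0)) {
    stop("band_centers must be strictly ascending")
  }
  if (time_step <= 0) stop("time_step must be positive")
  structure(list(values = values, band_centers = band_centers,
                 time_step = time_step, t0 = t0),
            class = "tf_envelope")
}

#' @export
print.tf_envelope <- function(x, ...) {
  cat(sprintf("<tf_envelope: %d bands x %d frames, step %.4g ms, %g-%g Hz>\n",
              nrow(x$values), ncol(x$values), x$time_step * 1000,
              min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

#' Auditory filterbank configuration
#'
#' Settings for the bank of bandpass filters behind the auditory spectrogram.
#' Defaults follow the recommended configuration: 16 third-order Butterworth
#' filters equally spaced on the ERB scale with ERB-rule bandwidths and a
#' 120-dB dynamic range. Gammatone filters (4th order, applied by FFT
#' convolution) are available as the physiologically classic alternative; the
#' two banks give near-equivalent roughness estimates.
#'
#' @param n_filters number of filters (1-64); 1 means the whole-signal envelope
#' @param filter_type `"butterworth"` or `"gammatone"`
#' @param scale center-frequency spacing scale: `"ERB"`, `"bark"` or `"log"`
#'   (log2-spaced)
#' @param bandwidth_mode `"ERB_rule"` (bandwidth from center frequency) or
#'   `"constant_Q"` (fixed semitone bandwidth)
#' @param q_semitones bandwidth in semitones when `bandwidth_mode = "constant_Q"`
#' @param cf_min,cf_max center-frequency range in Hz; `cf_max = NULL` defaults
#'   to `min(0.95 * Nyquist, 20000)` at application time
#' @param butterworth_order Butterworth filter order
#' @param gammatone_order gammatone filter order
#' @param dynamic_range dB below the spectrogram maximum at which envelope
#'   values are zeroed
#' @return an object of class `filterbank_config`
#' @export
filterbank_config <- function(n_filters = 16,
                              filter_type = c("butterworth", "gammatone"),
                              scale = c("ERB", "bark", "log"),
                              bandwidth_mode = c("ERB_rule", "constant_Q"),
                              q_semitones = 2,
                              cf_min = 20, cf_max = NULL,
                              butterworth_order = 3, gammatone_order = 4,
                              dynamic_range = 120) {
  filter_type <- match.arg(filter_type)
  scale <- match.arg(scale)
  bandwidth_mode <- match.arg(bandwidth_mode)
  if (n_filters < 1) stop("n_filters must be at least 1")
  if (cf_min <= 0) stop("cf_min must be positive")
  if (!is.null(cf_max) && cf_max <= cf_min) stop("cf_max must exceed cf_min")
  if (butterworth_order < 1 || gammatone_order < 1) stop("filter orders must be >= 1")
  if (bandwidth_mode == "constant_Q" && q_semitones <= 0) {
    stop("q_semitones must be positive")
  }
  structure(list(n_filters = n_filters, filter_type = filter_type,
                 scale = scale, bandwidth_mode = bandwidth_mode,
                 q_semitones = q_semitones, cf_min = cf_min, cf_max = cf_max,
                 butterworth_order = butterworth_order,
                 gammatone_order = gammatone_order,
                 dynamic_range = dynamic_range),
            class = "filterbank_config")
}

#' Design the filterbank for a sampling rate
#'
#' Places `n_filters` center frequencies equally spaced on the chosen
#' psychoacoustic scale between `cf_min` and `cf_max` (inclusive endpoints)
#' and attaches a bandwidth to each: the ERB rule (bandwidth grows with
#' center frequency) or a constant-Q semitone bandwidth. Corner frequencies
#' are clamped to (1 Hz, 0.97 * Nyquist); filters whose clamped passband
#' collapses below 1 Hz are dropped with a warning.
#'
#' @param config a [filterbank_config()]
#' @param sample_rate audio sampling rate in Hz
#' @return a data.frame with columns `center`, `bandwidth`, `lower`, `upper`
#' @export
make_filterbank <- function(config, sample_rate) {
  stopifnot(inherits(config, "filterbank_config"))
  nyq <- sample_rate / 2
  cf_max <- if (is.null(config$cf_max)) min(0.95 * nyq, 20000) else config$cf_max
  if (cf_max >= nyq) stop("cf_max must be below Nyquist")
  if (config$cf_min >= cf_max) stop("cf_min must be below cf_max")

  fwd <- switch(config$scale, ERB = hz_to_erb, bark = hz_to_bark, log = log2)
  inv <- switch(config$scale, ERB = erb_to_hz, bark = bark_to_hz,
                log = function(v) 2^v)
  centers <- if (config$n_filters == 1) {
    inv((fwd(config$cf_min) + fwd(cf_max)) / 2)
  } else {
    inv(seq(fwd(config$cf_min), fwd(cf_max), length.out = config$n_filters))
  }
  bw <- if (config$bandwidth_mode == "ERB_rule") {
    erb_bandwidth(centers)
  } else {
    constant_q_bandwidth(centers, config$q_semitones)
  }
  lower <- pmax(1, centers - bw / 2)
  upper <- pmin(0.97 * nyq, centers + bw / 2)
  ok <- (upper - lower) >= 1
  if (!any(ok)) stop("filterbank configuration yields no usable filters")
  if (any(!ok)) {
    warning(sum(!ok), " filter(s) with passband < 1 Hz after edge clamping dropped")
  }
  data.frame(center = centers[ok], bandwidth = bw[ok],
             lower = lower[ok], upper = upper[ok])
}

#' Gammatone impulse response
#'
#' Samples the gammatone kernel
#' `t^(order-1) * exp(-2*pi*bw*t) * cos(2*pi*cf*t)` at the audio rate, long
#' enough to span at least 10 periods of the center frequency, and rescales
#' it so the peak magnitude of its frequency response is 1 (unity passband
#' gain).
#'
#' @param cf center frequency in Hz (below Nyquist)
#' @param bw bandwidth in Hz
#' @param order gammatone order (4 approximates roex filter shapes)
#' @param sample_rate sampling rate in Hz
#' @return numeric impulse-response vector
#' @export
gammatone_kernel <- function(cf, bw, order = 4, sample_rate = 44100) {
  if (cf <= 0 || bw <= 0) stop("cf and bw must be positive")
  if (cf >= sample_rate / 2) stop("cf must be below Nyquist")
  # at least 10 periods of cf, and long enough for the gamma envelope to decay
  len_s <- max(10 / cf, (order + 4) / (2 * pi * bw) * 6)
  n <- ceiling(len_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  k <- t^(order - 1) * exp(-2 * pi * bw * t) * cos(2 * pi * cf * t)
  nfft <- 2^ceiling(log2(max(length(k) * 2, 1024)))
  gain <- max(Mod(stats::fft(c(k, numeric(nfft - length(k))))))
  k / gain
}

#' Apply one bandpass filter of the bank
#'
#' Butterworth filters are designed with corner frequencies
#' `center +/- bandwidth/2` (clamped) and applied forward-only (causal
#' recursion), matching a real-time filterbank; the group delay is small
#' relative to the analysis fragments and is not compensated. Gammatone
#' filters are applied by FFT convolution and the output is read from the
#' kernel's energy centroid onward so bands stay approximately aligned.
#'
#' @param signal an [audio_signal()]
#' @param center,bandwidth filter center and bandwidth, Hz
#' @param config a [filterbank_config()]
#' @return numeric vector, same length as the input samples
#' @export
apply_filter <- function(signal, center, bandwidth, config = filterbank_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  nyq <- sr / 2
  lo <- max(1, center - bandwidth / 2)
  hi <- min(0.97 * nyq, center + bandwidth / 2)
  if (hi - lo < 1) stop(sprintf("filter at %.1f Hz: passband collapsed after clamping", center))

  if (config$filter_type == "butterworth") {
    bf <- butter_bandpass_sos(config$butterworth_order, lo, hi, sr)
    y <- signal$samples
    for (s in bf$sos) {
      y <- as.numeric(signal::filter(signal::Arma(s$b, s$a), y))
    }
    y <- y * bf$gain
    if (!all(is.finite(y))) {
      stop(sprintf("filter at %.1f Hz is unstable at this sampling rate", center))
    }
    y
  } else {
    k <- gammatone_kernel(center, bandwidth, config$gammatone_order, sr)
    d <- round(sum(seq_along(k) * k^2) / sum(k^2))  # energy centroid delay
    n <- length(signal$samples)
    nfft <- 2^ceiling(log2(n + length(k) - 1))
    Y <- stats::fft(c(signal$samples, numeric(nfft - n))) *
         stats::fft(c(k, numeric(nfft - length(k))))
    y <- Re(stats::fft(Y, inverse = TRUE)) / nfft
    y[seq(d, length.out = n)]
  }
}

# Butterworth bandpass as cascaded second-order sections (biquads).
# A single transfer-function polynomial (as returned by signal::butter)
# loses precision catastrophically for narrow passbands far below Nyquist —
# exactly the low-frequency bands of an ERB-spaced bank at 44.1 kHz — so the
# digital poles are computed in closed form (analog prototype -> bandpass
# transform -> bilinear) and applied one conjugate pair at a time.
butter_bandpass_sos <- function(order, fl, fh, fs) {
  wl <- 2 * fs * tan(pi * fl / fs)   # prewarped analog edges, rad/s
  wh <- 2 * fs * tan(pi * fh / fs)
  w0sq <- wl * wh
  bw <- wh - wl
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_bp <- c(vapply(p_lp, function(p) {
    disc <- sqrt((p * bw)^2 - 4 * w0sq + 0i)
    (p * bw + c(1, -1) * disc) / 2
  }, complex(2)))
  z <- (2 * fs + p_bp) / (2 * fs - p_bp)
  if (any(Mod(z) >= 1)) stop("unstable Butterworth design (corners too close to 0 or Nyquist)")
  cplx <- z[Im(z) > 1e-10]
  realp <- sort(Re(z[abs(Im(z)) <= 1e-10]))
  sos <- c(
    lapply(cplx, function(p) list(b = c(1, 0, -1),
                                  a = c(1, -2 * Re(p), Mod(p)^2))),
    if (length(realp) > 0) {
      lapply(seq(1, length(realp), by = 2), function(i) {
        p1 <- realp[i]; p2 <- realp[min(i + 1, length(realp))]
        list(b = c(1, 0, -1), a = c(1, -(p1 + p2), p1 * p2))
      })
    }
  )
  fc <- fs / pi * atan(sqrt(w0sq) / (2 * fs))   # digital center frequency
  w <- 2 * pi * fc / fs
  H <- prod(vapply(sos, function(s) {
    e <- exp(-1i * w * (0:2))
    sum(s$b * e) / sum(s$a * e)
  }, complex(1)))
  list(sos = sos, gain = 1 / Mod(H), fc = fc)
}

#' Hilbert (analytic-signal) envelope
#'
#' Magnitude of the analytic signal, computed via the FFT construction:
#' double the positive-frequency half of the spectrum, zero the negative
#' half, inverse-transform and take the modulus. The envelope is pointwise
#' >= |x| and is used raw — no smoothing or downsampling — so all modulation
#' frequencies up to the audio Nyquist are preserved.
#'
#' @param x numeric vector (one filterbank band)
#' @return non-negative numeric vector, same length
#' @export
hilbert_envelope <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  if (n == 1) return(abs(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Auditory spectrogram
#'
#' Passes the signal through the filterbank and takes the Hilbert envelope of
#' each band, yielding a band x time matrix at the full audio rate. Envelope
#' values more than `dynamic_range` dB below the global maximum are set to
#' zero to suppress numerical noise. With `n_filters = 1` the single row is
#' the broadband envelope of the sound itself.
#'
#' @param signal an [audio_signal()]
#' @param config a [filterbank_config()]
#' @return a [tf_envelope()] with `time_step = 1/sample_rate`
#' @export
auditory_spectrogram <- function(signal, config = filterbank_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  bank <- make_filterbank(config, signal$sample_rate)
  env <- t(vapply(seq_len(nrow(bank)), function(b) {
    if (config$n_filters == 1) {
      hilbert_envelope(signal$samples)   # broadband: envelope of the sound itself
    } else {
      hilbert_envelope(apply_filter(signal, bank$center[b], bank$bandwidth[b],
                                    config))
    }
  }, numeric(length(signal$samples))))
  m <- max(env)
  if (m > 0) env[env < m * 10^(-config$dynamic_range / 20)] <- 0
  tf_envelope(env, bank$center, 1 / signal$sample_rate)
}
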