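#' Roughness weighting function
#'
#' Defines which modulation frequencies count as "rough". Three forms, all
#' peaking at 1 so that the normalized roughness statistic is bounded by
#' 100%:
#' \describe{
#'   \item{rectangular}{weight 1 on \[lo, hi\] (default 50-200 Hz), 0 outside}
#'   \item{gaussian_hz}{`exp(-(f - mean)^2 / (2 * sd_hz^2))` (default
#'     110 +/- 30 Hz)}
#'   \item{lognormal_semitones}{Gaussian on the semitone (log-frequency)
#'     axis: `exp(-d^2 / (2 * sd_semitones^2))` with
#'     `d = 12 * log2(f / mean)` (default 100 Hz +/- 8 semitones) — the
#'     recommended form, as it mimics natural auditory sensitivity to
#'     roughness and is least dependent on the range of computed modulation
#'     frequencies}
#' }
#' All forms return weight 0 below `rough_min_freq` (default 1 Hz):
#' near-DC modulation is discarded before normalization.
#'
#' @param form `"lognormal_semitones"`, `"gaussian_hz"` or `"rectangular"`
#' @param lo,hi rectangular cutoffs in Hz
#' @param mean peak modulation frequency in Hz (gaussian/lognormal)
#' @param sd_hz Gaussian standard deviation in Hz
#' @param sd_semitones lognormal standard deviation in semitones
#' @param rough_min_freq modulation frequencies below this get weight 0
#' @return an object of class `weight_spec`
#' @export
#' @examples
#' w <- weight_spec()                       # lognormal(100 Hz, 8 semitones)
#' evaluate_weights(w, c(0, 50, 100, 200))
weight_spec <- function(form = c("lognormal_semitones", "gaussian_hz",
                                 "rectangular"),
                        lo = 50, hi = 200, mean = NULL, sd_hz = 30,
                        sd_semitones = 8, rough_min_freq = 1) {
  form <- match.arg(form)
  if (is.null(mean)) mean <- if (form == "gaussian_hz") 110 else 100
  if (form == "rectangular" && lo >= hi) stop("need lo < hi")
  if (lo <= 0 && form == "rectangular") stop("lo must be positive")
  if (mean <= 0) stop("mean must be positive")
  if (sd_hz <= 0 || sd_semitones <= 0) stop("standard deviations must be positive")
  if (rough_min_freq < 0) stop("rough_min_freq must be non-negative")
  structure(list(form = form, lo = lo, hi = hi, mean = mean, sd_hz = sd_hz,
                 sd_semitones = sd_semitones, rough_min_freq = rough_min_freq),
            class = "weight_spec")
}

#' Evaluate a roughness weighting function
#'
#' @param weight a [weight_spec()]
#' @param mod_freqs ascending modulation frequencies in Hz
#' @return numeric vector of weights in \[0, 1\]
#' @export
evaluate_weights <- function(weight, mod_freqs) {
  stopifnot(inherits(weight, "weight_spec"))
  if (is.unsorted(mod_freqs)) stop("mod_freqs must be ascending")
  w <- switch(weight$form,
    rectangular = as.numeric(mod_freqs >= weight$lo & mod_freqs <= weight$hi),
    gaussian_hz = exp(-(mod_freqs - weight$mean)^2 / (2 * weight$sd_hz^2)),
    lognormal_semitones = ifelse(mod_freqs <= 0, 0,
      exp(-(12 * log2(pmax(mod_freqs, .Machine$double.xmin) / weight$mean))^2 /
            (2 * weight$sd_semitones^2)))
  )
  w[mod_freqs < weight$rough_min_freq] <- 0
  w
}

#' Full roughness-analysis configuration
#'
#' Bundles every tunable of the pipeline. The defaults reproduce the
#' recommended STFT configuration: STFT spectrogram (25-ms Hann window, 2-ms
#' step, magnitude, no log transforms), per-band 1D modulation spectra over
#' 200-ms fragments (`am_res = 5`), lognormal(100 Hz, 8 semitones) weighting
#' with modulation below 1 Hz discarded, median summary, and fragments more
#' than 40 dB quieter than the loudest fragment excluded. Switch
#' `spec_source = "audSpec"` for the auditory-filterbank route (16
#' Butterworth filters, ERB spacing and bandwidths, 120-dB dynamic range).
#'
#' @param spec_source `"STFT"` or `"audSpec"`
#' @param ms_type `"1D"` (per-band FFT, recommended) or `"2D"`
#' @param weight a [weight_spec()]
#' @param normalize if `TRUE` (default), roughness is the percentage of the
#'   modulation spectrum inside the weighting window; if `FALSE`, the raw
#'   weighted modulation energy is returned on an open scale
#' @param band_amplitude_weighting weight each band's contribution by its
#'   total envelope magnitude within the fragment
#' @param ms_taper taper applied to envelope fragments before the modulation
#'   FFT: `"hann"` (default) or `"none"`; see [mod_spectrum_1d()]
#' @param summary_stat `"median"` (the best predictor of perceived
#'   roughness), `"mean"` or `"max"`, taken over included fragments
#' @param silence_threshold_db fragments whose envelope RMS is more than this
#'   many dB below the loudest fragment are excluded (`Inf` disables)
#' @param fragmentation a [fragmentation_config()]
#' @param stft an [stft_config()]
#' @param filterbank a [filterbank_config()]
#' @return an object of class `roughness_config`
#' @export
roughness_config <- function(spec_source = c("STFT", "audSpec"),
                             ms_type = c("1D", "2D"),
                             weight = weight_spec(),
                             normalize = TRUE,
                             band_amplitude_weighting = FALSE,
                             ms_taper = c("hann", "none"),
                             summary_stat = c("median", "mean", "max"),
                             silence_threshold_db = 40,
                             fragmentation = fragmentation_config(),
                             stft = stft_config(),
                             filterbank = filterbank_config()) {
  spec_source <- match.arg(spec_source)
  ms_type <- match.arg(ms_type)
  summary_stat <- match.arg(summary_stat)
  ms_taper <- match.arg(ms_taper)
  stopifnot(inherits(weight, "weight_spec"),
            inherits(fragmentation, "fragmentation_config"),
            inherits(stft, "stft_config"),
            inherits(filterbank, "filterbank_config"))
  if (silence_threshold_db <= 0) stop("silence_threshold_db must be positive (use Inf to disable)")
  structure(list(spec_source = spec_source, ms_type = ms_type,
                 weight = weight, normalize = normalize,
                 band_amplitude_weighting = band_amplitude_weighting,
                 ms_taper = ms_taper,
                 summary_stat = summary_stat,
                 silence_threshold_db = silence_threshold_db,
                 fragmentation = fragmentation, stft = stft,
                 filterbank = filterbank),
            class = "roughness_config")
}

#' Roughness of one modulation spectrum
#'
#' The core statistic: per band,
#' `r_b = sum(ms_f * w_f) / sum(ms) * 100%`, where `ms_f` is the band's
#' modulation spectrum, `w_f` the weighting function, and the denominator
#' `sum(ms)` runs over the entire fragment's modulation spectrum (all bands),
#' so the per-band values add up to the fragment total
#' `r = sum(ms * w) / sum(ms) * 100%`. Modulation bins below
#' `rough_min_freq` are excluded from numerator and denominator. With
#' `normalize = FALSE` the un-normalized weighted energy `sum(ms * w)` is
#' returned instead (arbitrary units). A silent fragment (zero denominator)
#' yields `NA` roughness rather than an error.
#'
#' @param ms a `mod_spectrum`
#' @param config a [roughness_config()]
#' @return a list with `band_roughness` (per band) and `fragment_roughness`
#'   (scalar)
#' @export
roughness_of_spectrum <- function(ms, config = roughness_config()) {
  stopifnot(inherits(ms, "mod_spectrum"))
  keep <- ms$mod_freqs >= config$weight$rough_min_freq
  vals <- ms$values[, keep, drop = FALSE]
  if (config$band_amplitude_weighting) {
    band_amp <- rowSums(ms$values)
    vals <- vals * band_amp
  }
  w <- evaluate_weights(config$weight, ms$mod_freqs[keep])
  num_b <- as.numeric(vals %*% w)
  if (!config$normalize) {
    return(list(band_roughness = num_b, fragment_roughness = sum(num_b)))
  }
  denom <- sum(vals)
  if (denom <= 0) {
    return(list(band_roughness = rep(NA_real_, nrow(vals)),
                fragment_roughness = NA_real_))
  }
  r_b <- num_b / denom * 100
  list(band_roughness = r_b, fragment_roughness = sum(r_b))
}

#' Estimate the roughness of a sound
#'
#' The main entry point. Builds a spectrogram (STFT or auditory filterbank),
#' splits it into fragments, computes a temporal modulation spectrum per
#' fragment, and scores each fragment as the weighted percentage of its
#' modulation spectrum falling in the rough range of modulation frequencies.
#' Fragments are excluded from the summary when their envelope RMS falls more
#' than `silence_threshold_db` below the loudest fragment (near-silent audio
#' otherwise registers as very rough), or when less than half of their
#' duration overlaps the voiced intervals in `mask`. The summary is the
#' median (by default) over included fragments.
#'
#' @param x an [audio_signal()] or a path to a WAV file
#' @param config a [roughness_config()]
#' @param mask optional voicing mask: a two-column matrix or data.frame of
#'   (start, end) times in seconds; fragments overlapping the voiced
#'   intervals for less than half their duration are excluded
#' @return an object of class `roughness`: a list with `fragment_times` (s),
#'   `fragment_roughness` (%), `band_roughness` (band x fragment matrix),
#'   `band_centers`, `fragment_rms`, `included` (logical), `summary` (%,
#'   `NA` if no fragment qualifies), `mod_spectra` (per-fragment
#'   `mod_spectrum` objects), `config`, and `source`
#' @export
#' @examples
#' am <- synth_stimulus("am_tone", freq = 2000, am_rate = 70, am_depth = 1)
#' r <- roughness(am)
#' r$summary
roughness <- function(x, config = roughness_config(), mask = NULL) {
  if (is.character(x)) x <- read_wav(x)
  stopifnot(inherits(x, "audio_signal"), inherits(config, "roughness_config"))

  env <- if (config$spec_source == "STFT") {
    stft(x, config$stft)
  } else {
    auditory_spectrogram(x, config$filterbank)
  }
  frags <- fragment(env, config$fragmentation)
  spectra <- lapply(frags, function(fr) {
    if (config$ms_type == "1D") {
      mod_spectrum_1d(fr, exponent = 1, taper = config$ms_taper)
    } else {
      mod_spectrum_2d(fr, exponent = 1, taper = config$ms_taper)
    }
  })
  scored <- lapply(spectra, roughness_of_spectrum, config = config)

  frag_r <- vapply(scored, `[[`, numeric(1), "fragment_roughness")
  band_r <- vapply(scored, `[[`, numeric(length(scored[[1]]$band_roughness)),
                   "band_roughness")
  band_r <- matrix(band_r, ncol = length(scored))
  rms <- vapply(spectra, `[[`, numeric(1), "fragment_rms")
  times <- vapply(spectra, `[[`, numeric(1), "fragment_start")

  included <- !is.na(frag_r)
  if (is.finite(config$silence_threshold_db) && any(rms > 0)) {
    included <- included &
      20 * log10(pmax(rms, .Machine$double.xmin) / max(rms)) >
        -config$silence_threshold_db
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)[, 1:2, drop = FALSE]
    frag_dur <- vapply(frags, function(fr) ncol(fr$values) * fr$time_step,
                       numeric(1))
    voiced_overlap <- vapply(seq_along(frags), function(i) {
      t0 <- times[i]; t1 <- times[i] + frag_dur[i]
      sum(pmax(0, pmin(mask[, 2], t1) - pmax(mask[, 1], t0)))
    }, numeric(1))
    included <- included & (voiced_overlap >= frag_dur / 2)
  }

  res <- structure(
    list(fragment_times = times, fragment_roughness = frag_r,
         band_roughness = band_r, band_centers = spectra[[1]]$band_centers,
         fragment_rms = rms, included = included, summary = NA_real_,
         mod_spectra = spectra, config = config,
         source = if (is.null(x$source_path)) "<audio_signal>" else x$source_path,
         signal = x),
    class = "roughness")
  res$summary <- summarize(res, config$summary_stat)
  res
}

#' Summarize a roughness contour into one value
#'
#' @param result a [roughness()] object
#' @param stat `"median"`, `"mean"` or `"max"` over included fragments; the
#'   median tracks perceived roughness best
#' @return a single roughness value (%), or `NA` if no fragment is included
#' @export
summarize <- function(result, stat = c("median", "mean", "max")) {
  stopifnot(inherits(result, "roughness"))
  stat <- match.arg(stat)
  v <- result$fragment_roughness[result$included]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  switch(stat, median = stats::median(v), mean = mean(v), max = max(v))
}

#' @export
print.roughness <- function(x, ...) {
  cat("Acoustic roughness estimate\n")
  cat(sprintf("  source:  %s\n", x$source))
  cat(sprintf("  pipeline: %s / %s FFT, %s weighting\n",
              x$config$spec_source, x$config$ms_type, x$config$weight$form))
  cat(sprintf("  fragments: %d (%d included)\n",
              length(x$fragment_roughness), sum(x$included)))
  cat(sprintf("  summary (%s): %s\n", x$config$summary_stat,
              if (is.na(x$summary)) "undefined (no included fragments)"
              else sprintf("%.2f%%", x$summary)))
  invisible(x)
}

#' @export
summary.roughness <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Roughness contour (%s pipeline): %d fragments, summary %s = %s\n\n",
              object$config$spec_source, nrow(df), object$config$summary_stat,
              if (is.na(object$summary)) "NA"
              else sprintf("%.2f%%", object$summary)))
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.roughness <- function(x, ...) {
  data.frame(t_start_s = x$fragment_times,
             rms = x$fragment_rms,
             included = x$included,
             roughness_pct = x$fragment_roughness)
}
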