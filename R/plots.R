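#' Diagnostic plots for a roughness analysis
#'
#' Four views of the same result, all base-graphics rasters:
#' \describe{
#'   \item{contour_overlay}{STFT spectrogram of the analyzed sound with the
#'     fragment roughness contour drawn over it; excluded fragments appear as
#'     gaps}
#'   \item{roughness_spectrogram}{per-band roughness (band x fragment) on
#'     time/frequency axes — where in the spectrum the modulation lives}
#'   \item{modulation_spectrogram}{per-fragment modulation spectra averaged
#'     across acoustic bands (modulation frequency x time) — how fast the
#'     envelopes fluctuate at each moment}
#'   \item{weight_comparison}{the three weighting-function forms on a common
#'     modulation-frequency axis}
#' }
#' Plotting is side-effect-only: the result object is not modified.
#'
#' @param x a [roughness()] object
#' @param kind which view to draw
#' @param ... ignored
#' @return `x`, invisibly
#' @export
plot.roughness <- function(x, kind = c("contour_overlay",
                                       "roughness_spectrogram",
                                       "modulation_spectrogram",
                                       "weight_comparison"), ...) {
  kind <- match.arg(kind)
  if (length(x$fragment_roughness) == 0) stop("empty roughness result")
  pal <- grDevices::hcl.colors(128, "viridis")
  frag_dur <- 1 / x$config$fragmentation$am_res
  t_mid <- x$fragment_times + frag_dur / 2

  if (kind == "contour_overlay") {
    sp <- stft(x$signal, x$config$stft)
    z <- t(sp$values)
    z <- log10(z + max(z) * 1e-6)   # display only; analysis stays linear
    tt <- sp$t0 + (seq_len(nrow(z)) - 1) * sp$time_step
    graphics::image(tt, sp$band_centers, z, col = pal,
                    xlab = "Time (s)", ylab = "Frequency (Hz)",
                    main = "Spectrogram with roughness contour")
    r <- x$fragment_roughness
    r[!x$included] <- NA
    graphics::lines(t_mid, r / 100 * max(sp$band_centers),
                    col = "white", lwd = 2)
    graphics::points(t_mid, r / 100 * max(sp$band_centers),
                     col = "white", pch = 16)
    graphics::axis(4, at = seq(0, max(sp$band_centers), length.out = 5),
                   labels = seq(0, 100, length.out = 5))
    graphics::mtext("Roughness (%)", side = 4, line = 2)
  } else if (kind == "roughness_spectrogram") {
    z <- t(x$band_roughness)
    z[!x$included, ] <- NA
    graphics::image(t_mid, x$band_centers, z, col = pal,
                    xlab = "Time (s)", ylab = "Band center (Hz)",
                    main = "Roughness spectrogram (per-band roughness, %)")
  } else if (kind == "modulation_spectrogram") {
    mf <- x$mod_spectra[[1]]$mod_freqs
    z <- vapply(x$mod_spectra, function(s) {
      v <- colMeans(s$values)
      if (length(v) != length(mf)) {
        v <- stats::approx(s$mod_freqs, v, xout = mf, rule = 2)$y
      }
      v
    }, numeric(length(mf)))
    z <- t(z)
    z[!x$included, ] <- NA
    graphics::image(t_mid, mf, z, col = pal,
                    xlab = "Time (s)", ylab = "Modulation frequency (Hz)",
                    main = "Modulation spectrogram (band-averaged)")
  } else {
    f <- seq(1, 500, by = 0.5)
    graphics::plot(f, evaluate_weights(weight_spec("rectangular"), f),
                   type = "l", col = "grey50", lwd = 2, ylim = c(0, 1.05),
                   xlab = "Modulation frequency (Hz)", ylab = "Weight",
                   main = "Roughness weighting functions")
    graphics::lines(f, evaluate_weights(weight_spec("gaussian_hz"), f),
                    col = "forestgreen", lwd = 2)
    graphics::lines(f, evaluate_weights(weight_spec("lognormal_semitones"), f),
                    col = "royalblue", lwd = 2)
    graphics::legend("topright", bty = "n", lwd = 2,
                     col = c("grey50", "forestgreen", "royalblue"),
                     legend = c("rectangular 50-200 Hz",
                                "Gaussian 110 ± 30 Hz",
                                "lognormal 100 Hz ± 8 semitones"))
  }
  invisible(x)
}

#' Render a roughness plot to a PNG file
#'
#' Thin wrapper around [plot.roughness()] writing
#' `<input stem>_<kind>.png` (or an explicit `output_path`).
#'
#' @param result a [roughness()] object
#' @param kind plot kind, see [plot.roughness()]
#' @param output_path output PNG path; default derives from the input name
#' @param width,height,res device settings passed to [grDevices::png()]
#' @return the output path, invisibly
#' @export
render <- function(result, kind = c("contour_overlay",
                                    "roughness_spectrogram",
                                    "modulation_spectrogram",
                                    "weight_comparison"),
                   output_path = NULL, width = 1200, height = 700, res = 120) {
  kind <- match.arg(kind)
  stopifnot(inherits(result, "roughness"))
  if (is.null(output_path)) {
    stem <- if (identical(result$source, "<audio_signal>")) "roughness"
            else tools::file_path_sans_ext(basename(result$source))
    output_path <- paste0(stem, "_", kind, ".png")
  }
  grDevices::png(output_path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot(result, kind = kind)
  invisible(output_path)
}
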