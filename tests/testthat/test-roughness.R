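ms_of <- function(values, mod_freqs, band_centers = seq_len(nrow(values)) * 100) {
  structure(list(values = values, mod_freqs = mod_freqs,
                 band_centers = band_centers, fragment_start = 0,
                 fragment_rms = 1),
            class = "mod_spectrum")
}

mock_result <- function(vals, included = rep(TRUE, length(vals))) {
  structure(list(fragment_roughness = vals, included = included),
            class = "roughness")
}

test_that("weighting functions evaluate to their defining forms", {
  rect <- weight_spec("rectangular", lo = 50, hi = 200)
  expect_equal(evaluate_weights(rect, c(49, 50, 200, 201)), c(0, 1, 1, 0))
  gauss <- weight_spec("gaussian_hz")
  expect_equal(evaluate_weights(gauss, 110), 1)          # peak at the mean
  expect_equal(evaluate_weights(gauss, 140), exp(-0.5))  # one SD away
  logn <- weight_spec("lognormal_semitones")
  expect_equal(evaluate_weights(logn, 100), 1)
  # one octave above the 100-Hz mean = 12 semitones, SD 8
  expect_equal(evaluate_weights(logn, 200), exp(-0.5 * (12 / 8)^2))
  expect_equal(evaluate_weights(logn, 200), 0.3247, tolerance = 1e-3)
  expect_equal(evaluate_weights(logn, 0), 0)             # undefined log -> 0
  # everything below rough_min_freq is discarded
  expect_equal(evaluate_weights(logn, c(0.2, 0.9)), c(0, 0))
  # weights bounded in [0, 1] with peak 1 for every form
  f <- seq(0, 1000, by = 0.5)
  for (w in list(rect, gauss, logn)) {
    v <- evaluate_weights(w, f)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(max(v), 1)
  }
  expect_error(weight_spec("rectangular", lo = 300, hi = 200), "lo < hi")
  expect_error(weight_spec(sd_hz = -1), "positive")
})

test_that("the roughness statistic is the weighted share of the modulation spectrum", {
  cfg <- roughness_config(weight = weight_spec("rectangular", lo = 50,
                                               hi = 200))
  # all energy inside the weighting window -> 100%
  all_in <- ms_of(matrix(c(0, 2, 3, 0), 1), c(0, 60, 100, 300))
  expect_equal(roughness_of_spectrum(all_in, cfg)$fragment_roughness, 100)
  # all energy where the weight is zero -> 0%
  all_out <- ms_of(matrix(c(0, 0, 0, 5), 1), c(0, 60, 100, 300))
  expect_equal(roughness_of_spectrum(all_out, cfg)$fragment_roughness, 0)
  # two equal cells, one weighted 1 and one weighted 0 -> 50%
  half <- ms_of(matrix(c(0, 4, 0, 4), 1), c(0, 100, 300, 500))
  expect_equal(roughness_of_spectrum(half, cfg)$fragment_roughness, 50)
  # silent fragment: undefined, flagged as NA rather than an error
  silent <- ms_of(matrix(0, 2, 4), c(0, 60, 100, 300))
  out <- roughness_of_spectrum(silent, cfg)
  expect_true(is.na(out$fragment_roughness))
  expect_true(all(is.na(out$band_roughness)))
  # normalization off: raw weighted energy, open scale
  cfg_raw <- roughness_config(weight = weight_spec("rectangular", lo = 50,
                                                   hi = 200),
                              normalize = FALSE)
  expect_equal(roughness_of_spectrum(half, cfg_raw)$fragment_roughness, 4)
})

test_that("per-band roughness sums to the fragment total", {
  x <- synth_stimulus("am_tone", duration = 1, freq = 2000, am_rate = 70,
                      am_depth = 1)
  for (src in c("STFT", "audSpec")) {
    r <- roughness(x, roughness_config(src))
    expect_lt(max(abs(colSums(r$band_roughness) - r$fragment_roughness)),
              1e-9)
    expect_true(all(r$fragment_roughness >= 0 &
                    r$fragment_roughness <= 100))
  }
})

test_that("band-amplitude weighting shifts weight toward loud bands", {
  vals <- rbind(c(0, 1, 1), c(0, 9, 1))      # band 2 is 5x louder overall
  ms <- ms_of(vals, c(0, 100, 500))
  cfg <- roughness_config(weight = weight_spec("rectangular", lo = 50,
                                               hi = 200))
  plain <- roughness_of_spectrum(ms, cfg)
  cfg_w <- roughness_config(weight = cfg$weight,
                            band_amplitude_weighting = TRUE)
  amped <- roughness_of_spectrum(ms, cfg_w)
  share_plain <- plain$band_roughness[2] / plain$fragment_roughness
  share_amped <- amped$band_roughness[2] / amped$fragment_roughness
  expect_gt(share_amped, share_plain)
})

test_that("a weight of one everywhere above the floor scores every fragment 100%", {
  cfg <- roughness_config(weight = weight_spec("rectangular", lo = 1,
                                               hi = 1e9))
  x <- synth_stimulus("am_tone", duration = 0.6, freq = 1000, am_rate = 70,
                      am_depth = 0.5)
  r <- roughness(x, cfg)
  expect_equal(r$fragment_roughness, rep(100, 3), tolerance = 1e-9)
})

test_that("roughness is invariant to waveform gain", {
  x <- synth_stimulus("am_tone", duration = 1, freq = 2000, am_rate = 70,
                      am_depth = 0.7, peak_amplitude = 0.09)
  x10 <- audio_signal(x$samples * 10, x$sample_rate)
  for (src in c("STFT", "audSpec")) {
    cfg <- roughness_config(src)
    r1 <- roughness(x, cfg)$fragment_roughness
    r10 <- roughness(x10, cfg)$fragment_roughness
    expect_lt(max(abs(r1 - r10)), 1e-6)
  }
})

test_that("modulation in the rough range beats no modulation, and the lognormal window is rate-tuned", {
  for (src in c("STFT", "audSpec")) {
    cfg <- roughness_config(src)
    am <- roughness(synth_stimulus("am_tone", freq = 2000, am_rate = 70,
                                   am_depth = 1), cfg)$summary
    flat <- roughness(synth_stimulus("pure_tone", freq = 2000), cfg)$summary
    expect_gt(am, flat)
    r_at <- function(rate) {
      roughness(synth_stimulus("am_tone", freq = 2000, am_rate = rate,
                               am_depth = 1), cfg)$summary
    }
    r100 <- r_at(100)
    expect_gt(r100, r_at(8))
    expect_gt(r100, r_at(800))
  }
})

test_that("normalized roughness saturates with AM depth but separates modulated from flat", {
  # every non-DC envelope component scales with depth, so the normalized
  # share is near-constant for any positive depth; only the 0-vs-positive
  # contrast is large
  r <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    roughness(synth_stimulus("am_tone", freq = 2000, am_rate = 70,
                             am_depth = d))$summary
  }, numeric(1))
  expect_lt(r[1], 5)
  expect_true(all(r[-1] > 50))
  expect_lt(diff(range(r[-1])) / mean(r[-1]), 0.1)
  w70 <- evaluate_weights(weight_spec(), 70)
  expect_equal(mean(r[-1]) / 100, w70, tolerance = 0.05)
})

test_that("fragment times follow the amRes grid", {
  x <- synth_stimulus("am_tone", duration = 1, freq = 1000, am_rate = 70,
                      am_depth = 1)
  r <- roughness(x)
  # times sit on the frame grid (hop = round(2 ms * sr) samples), so they
  # deviate from the nominal 200-ms spacing by the rounding of the hop
  expect_equal(r$fragment_times, seq(0, 0.8, by = 0.2), tolerance = 5e-3)
})

test_that("near-silent fragments are excluded and the summary uses the rest", {
  x <- synth_stimulus("am_tone", duration = 1, freq = 1000, am_rate = 70,
                      am_depth = 1)
  quiet <- x$samples * 1e-4                      # -80 dB
  sig <- audio_signal(c(x$samples, quiet), 44100)
  r <- roughness(sig)
  expect_equal(sum(r$included), 5)               # only the loud first half
  expect_true(all(r$included[1:5]))
  expect_equal(r$summary, stats::median(r$fragment_roughness[1:5]))
  # threshold disabled: everything included
  r_all <- roughness(sig, roughness_config(silence_threshold_db = Inf))
  expect_equal(sum(r_all$included), 10)
  # digital silence: roughness undefined, flagged not thrown
  dead <- audio_signal(numeric(44100) + 0, 44100)
  r0 <- roughness(dead)
  expect_equal(sum(r0$included), 0)
  expect_true(is.na(r0$summary))
})

test_that("a voicing mask excludes fragments with under half voiced overlap", {
  x <- synth_stimulus("am_tone", duration = 1, freq = 1000, am_rate = 70,
                      am_depth = 1)
  r <- roughness(x, mask = cbind(0, 0.5))       # voiced first half only
  expect_equal(r$included, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # fragment 3 (0.4-0.6 s) has exactly half overlap -> included
})

test_that("summary statistics aggregate included fragments only", {
  expect_equal(summarize(mock_result(37.2), "median"), 37.2)
  expect_equal(summarize(mock_result(c(10, 20, 90)), "median"), 20)
  expect_equal(summarize(mock_result(c(10, 20, 90)), "mean"), 40)
  expect_equal(summarize(mock_result(c(10, 20, 90)), "max"), 90)
  expect_equal(summarize(mock_result(c(10, 20, 90),
                                     included = c(TRUE, FALSE, TRUE)),
                         "mean"), 50)
  expect_true(is.na(summarize(mock_result(c(10, 20),
                                          included = c(FALSE, FALSE)))))
})

test_that("roughness estimates are robust to the sampling rate", {
  for (src in c("STFT", "audSpec")) {
    cfg <- roughness_config(src)
    r8 <- roughness(synth_stimulus("am_tone", freq = 2000, am_rate = 70,
                                   am_depth = 1, sample_rate = 8000),
                    cfg)$summary
    r44 <- roughness(synth_stimulus("am_tone", freq = 2000, am_rate = 70,
                                    am_depth = 1, sample_rate = 44100),
                     cfg)$summary
    expect_lt(abs(r8 - r44) / r44, 0.10)
  }
})

test_that("print, summary and as.data.frame expose the contour", {
  r <- roughness(synth_stimulus("am_tone", duration = 0.4, freq = 1000,
                                am_rate = 70, am_depth = 1))
  expect_output(print(r), "summary \\(median\\)")
  df <- as.data.frame(r)
  expect_named(df, c("t_start_s", "rms", "included", "roughness_pct"))
  expect_equal(nrow(df), length(r$fragment_roughness))
  expect_output(out <- summary(r), "fragments")
  expect_equal(out$roughness_pct, r$fragment_roughness)
})
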