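test_that("filterbank centers are equally spaced on the chosen scale", {
  cfg <- filterbank_config(n_filters = 3, scale = "ERB", cf_min = 100,
                           cf_max = 1000)
  bank <- make_filterbank(cfg, 44100)
  expect_equal(nrow(bank), 3)
  expect_equal(bank$center[1], 100)
  expect_equal(bank$center[3], 1000)
  expect_equal(bank$center[2],
               erb_to_hz((hz_to_erb(100) + hz_to_erb(1000)) / 2))
  # log scale: geometric midpoint
  bank_log <- make_filterbank(
    filterbank_config(n_filters = 3, scale = "log", cf_min = 100,
                      cf_max = 1600), 44100)
  expect_equal(bank_log$center[2], sqrt(100 * 1600))
})

test_that("ERB-rule bandwidths grow with center frequency across the bank", {
  bank <- make_filterbank(filterbank_config(n_filters = 16), 44100)
  expect_equal(nrow(bank), 16)
  expect_true(all(diff(bank$bandwidth) > 0))
  expect_equal(bank$bandwidth, erb_bandwidth(bank$center))
})

test_that("degenerate filterbank configurations error out", {
  # sub-semitone constant-Q filters collapse below the 1-Hz passband floor
  cfg <- filterbank_config(n_filters = 2, bandwidth_mode = "constant_Q",
                           q_semitones = 1e-4, cf_min = 50, cf_max = 100)
  expect_error(make_filterbank(cfg, 44100), "no usable filters")
  expect_error(make_filterbank(filterbank_config(cf_min = 100, cf_max = 5000),
                               8000), "Nyquist")
})

test_that("gammatone kernel follows the gamma-envelope cosine form", {
  k <- gammatone_kernel(100, erb_bandwidth(100), order = 4,
                        sample_rate = 44100)
  expect_equal(k[1], 0)                       # t^3 factor at t = 0
  expect_gte(length(k), 10 / 100 * 44100)     # at least 10 periods of cf
  # frequency response peaks at (slightly below) the center frequency
  k1 <- gammatone_kernel(1000, erb_bandwidth(1000), sample_rate = 44100)
  nfft <- 2^16
  H <- Mod(stats::fft(c(k1, numeric(nfft - length(k1)))))
  f_peak <- (which.max(H[1:(nfft / 2)]) - 1) * 44100 / nfft
  expect_lt(abs(f_peak - 1000), 10)
  expect_equal(max(H), 1, tolerance = 1e-3)   # unity passband gain
  expect_error(gammatone_kernel(30000, 100, sample_rate = 44100), "Nyquist")
})

test_that("bandpass filters pass their center and reject distant tones", {
  tone_at <- function(f) synth_stimulus("pure_tone", duration = 0.5, freq = f,
                                        ramp_ms = 0)
  for (type in c("butterworth", "gammatone")) {
    cfg <- filterbank_config(filter_type = type)
    rms <- function(v) sqrt(mean(v^2))
    x_in <- tone_at(1000)
    y_pass <- apply_filter(x_in, 1000, erb_bandwidth(1000), cfg)
    expect_gte(rms(y_pass[4410:22050]) / rms(x_in$samples), 0.7)
    x_far <- tone_at(8000)   # 3 octaves above the filter
    y_stop <- apply_filter(x_far, 1000, erb_bandwidth(1000), cfg)
    expect_lt(rms(y_stop) / rms(x_far$samples), 0.05)
    y_zero <- apply_filter(audio_signal(numeric(1000) + 0, 44100), 1000,
                           erb_bandwidth(1000), cfg)
    expect_equal(max(abs(y_zero)), 0)
  }
})

test_that("narrow low-frequency Butterworth bands stay numerically stable", {
  # worst case of an ERB bank at 44.1 kHz: the 20-Hz filter
  x <- synth_stimulus("pure_tone", duration = 1, freq = 20, ramp_ms = 0,
                      peak_amplitude = 1)
  y <- apply_filter(x, 20, erb_bandwidth(20), filterbank_config())
  expect_true(all(is.finite(y)))
  expect_lt(max(abs(y)), 2)
  expect_gt(sqrt(mean(y[22050:44100]^2)), 0.5)  # tone at center passes
})

test_that("Hilbert envelope bounds the signal and tracks beats", {
  t <- (0:22049) / 44100
  x <- 0.8 * sin(2 * pi * 500 * t)
  env <- hilbert_envelope(x)
  core <- 1103:20947  # 5% edge margins
  expect_lt(max(abs(env[core] - 0.8)) / 0.8, 0.01)
  expect_true(all(env >= abs(x) - 1e-9))
  expect_equal(hilbert_envelope(-x), env)

  tt <- synth_stimulus("two_tone", duration = 1, freq = 100, freq2 = 110)
  e <- hilbert_envelope(tt$samples)
  spec <- dft_magnitude_oracle(e, taper = "none")
  expect_equal(which.max(spec[2:500]), 10)  # beats at f2 - f1 = 10 Hz
})

test_that("auditory spectrogram is homogeneous and localizes tone energy", {
  cfg <- filterbank_config()
  x <- synth_stimulus("am_tone", duration = 0.3, freq = 1000, am_rate = 70,
                      am_depth = 0.8)
  env1 <- auditory_spectrogram(x, cfg)
  x10 <- audio_signal(x$samples * 10, x$sample_rate)
  env10 <- auditory_spectrogram(x10, cfg)
  expect_equal(env10$values, env1$values * 10, tolerance = 1e-9)

  bank <- make_filterbank(cfg, 44100)
  target <- 8  # tone exactly at a band center
  tone <- synth_stimulus("pure_tone", duration = 0.3,
                         freq = bank$center[target])
  env <- auditory_spectrogram(tone, cfg)
  expect_equal(which.max(rowMeans(env$values)), target)
})

test_that("silence maps to an all-zero auditory spectrogram", {
  z <- audio_signal(numeric(8820) + 0, 44100)
  env <- auditory_spectrogram(z, filterbank_config(n_filters = 4,
                                                   cf_max = 8000))
  expect_equal(max(env$values), 0)
})

test_that("a single filter reduces to the broadband envelope of the sound", {
  x <- synth_stimulus("am_tone", duration = 0.3, freq = 1000, am_rate = 40,
                      am_depth = 1)
  env <- auditory_spectrogram(x, filterbank_config(n_filters = 1))
  expect_equal(nrow(env$values), 1)
  # identical up to the dynamic-range floor zeroing denormal-scale values
  expect_lt(max(abs(env$values[1, ] - hilbert_envelope(x$samples))),
            1e-6 * max(env$values))
})

test_that("the band nearest an AM carrier fluctuates at the AM rate", {
  x <- synth_stimulus("am_tone", duration = 1, freq = 2000, am_rate = 70,
                      am_depth = 1)
  env <- auditory_spectrogram(x, filterbank_config())
  b <- which.max(rowMeans(env$values))
  spec <- dft_magnitude_oracle(env$values[b, ], taper = "none")
  expect_equal(which.max(spec[2:300]), 70)   # 1-Hz bins over 1 s
})

test_that("Butterworth and gammatone banks agree on downstream roughness", {
  specs <- expand.grid(rate = c(20, 70, 150), carrier = c(500, 2000))
  r <- vapply(c("butterworth", "gammatone"), function(type) {
    cfg <- roughness_config("audSpec",
                            filterbank = filterbank_config(filter_type = type))
    vapply(seq_len(nrow(specs)), function(i) {
      s <- synth_stimulus("am_tone", duration = 0.5, freq = specs$carrier[i],
                          am_rate = specs$rate[i], am_depth = 0.8)
      roughness(s, cfg)$summary
    }, numeric(1))
  }, numeric(nrow(specs)))
  expect_gt(stats::cor(r[, 1], r[, 2]), 0.9)
})
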