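---
title: "Measuring voice roughness from modulation spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring voice roughness from modulation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughvoc)
```

## The model

Perceived roughness tracks how strongly the envelopes of cochlear frequency
bands fluctuate at rates of roughly 15–300 Hz. `roughvoc` operationalizes
this as a three-stage pipeline.

**Stage 1 — band envelopes.** Two interchangeable front ends produce a
band × time matrix of non-negative envelope values (`tf_envelope`):

* *Auditory spectrogram* (`auditory_spectrogram()`): a bank of bandpass
  filters with center frequencies equally spaced on the ERB scale (bark and
  log2 spacing are available), bandwidths from the ERB rule
  `24.7 (4.37 cf/1000 + 1)` or a constant-Q semitone rule, followed by the
  Hilbert envelope of each band at the full audio rate — no smoothing, no
  downsampling. Third-order Butterworth filters are the default (16 of
  them); fourth-order gammatones applied by FFT convolution are the
  physiologically classic alternative, and the test suite checks that the
  two banks produce downstream roughness values correlating above 0.9 on a
  small AM-tone battery.
* *STFT spectrogram* (`stft()`): magnitude spectrogram with a 25-ms Hann
  window and 2-ms step. The step sets the rate at which band envelopes are
  sampled, so the representable modulation range ends at
  `1000/(2·step)` = 250 Hz; `validate_stft_settings()` reports the three
  constraints that govern window/step choice (step ≤ `1000/mod_max/2`;
  window ≥ one period of the lowest f0; window ideally below two periods of
  the fastest modulation, hard ceiling `1000/30` ms) as warnings, since
  they cannot all hold simultaneously.

**Stage 2 — modulation spectra.** The envelope matrix is cut into
contiguous fragments of `1/am_res` seconds (default 200 ms, i.e. five
roughness measurements per second; a trailing remainder shorter than half a
fragment is merged into the previous one). For each fragment and band, the
band's time-mean is removed, a Hann taper applied, and an FFT taken; the
magnitudes at non-negative modulation frequencies form the fragment's
modulation spectrum (`mod_spectrum_1d()`). A 2D-FFT route
(`mod_spectrum_2d()`) folds negative and positive temporal modulation
frequencies and collapses the spectral-modulation axis; it is provided for
comparison but the per-band 1D route is the default — it keeps the band
axis interpretable and performs better as a predictor of perceived
roughness.

**Stage 3 — the roughness statistic.** With a weighting function `w` over
modulation frequency (peak value 1), per band
`r_b = Σ(ms_f · w_f)/Σ(ms) · 100%`; the denominator runs over the whole
fragment's modulation spectrum, so band values sum exactly to the fragment
total `r = Σ(ms·w)/Σ(ms) · 100%` (asserted to 1e-9 in the tests).
Modulation bins below `rough_min_freq` (default 1 Hz) are excluded from
numerator and denominator. Fragments whose envelope RMS falls more than
40 dB below the loudest fragment, or that overlap a supplied voicing mask
for less than half their duration, are excluded; the summary is the median
over the rest (the median tracks perceived roughness better than the mean
or maximum).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `spec_source` | STFT | — | faster; audSpec is one switch away |
| `window_length`, `step` | 25, 2 | ms | best-performing STFT geometry; step sets the 250-Hz modulation ceiling |
| `n_filters` | 16 | — | performance saturates between 16 and 64 filters |
| `scale`, `bandwidth_mode` | ERB, ERB rule | — | critical-band-like spacing and widths |
| `dynamic_range` | 120 | dB | floors numerical noise in envelopes |
| `am_res` | 5 | 1/s | 200-ms fragments: accuracy is flat down to ~40-ms fragments, and contours stay interpretable |
| weighting | lognormal, 100 Hz ± 8 semitones | — | matches auditory roughness sensitivity; least sensitive to the computed modulation range |
| `rough_min_freq` | 1 | Hz | drops near-DC drift before normalization |
| `silence_threshold_db` | 40 | dB | near-silent fragments otherwise register as very rough |
| `summary_stat` | median | — | robust to one-off transients |
| `normalize` | TRUE | — | proportions make estimates level- and rate-robust; `FALSE` returns raw weighted energy on an open scale |

No input normalization is needed: because roughness is a proportion, it is
invariant to waveform gain (tested to 1e-6 under a ×10 gain) and robust to
sampling rate (8 vs 44.1 kHz renderings agree within 10% in the tests).

## The synthetic stimuli, and what passing tests do and do not show

`synth_stimulus()` generates the test battery: pure tones, AM tones,
two-tone beat pairs (100 + 110 Hz → envelope beats at 10 Hz), harmonic
vowel-like tones (f0 with 1/k roll-off, optionally AM), click trains and
white noise. All components use cosine phase, so fixtures are bit-identical
across runs; a 10-ms raised-cosine ramp avoids onset transients (clicks are
exact single-sample impulses and are not ramped). `synthetic_battery()`
fixes the pipeline-comparison set: carriers {500, 2000} Hz × 10 AM rates
log-uniformly spanning 5–400 Hz (log-uniform because modulation sensitivity
is organized on a log-frequency axis) × depths cycling {0.25…1}.

These stimuli are deliberately clean: no background noise, no reverberation,
no f0 variation, no subharmonics or deterministic chaos, no competing
sources. Passing tests therefore demonstrate the *mechanics* — correct
spectra, correct statistic, correct gating — not perceptual validity on
natural voices, which requires rated corpora. Two behavioral consequences of
that cleanliness are worth spelling out, because the test suite documents
them honestly:

* **Depth saturation.** For a noiseless AM tone every non-DC envelope
  component scales linearly with modulation depth, so the normalized
  statistic is nearly constant for any positive depth (≈ the weight value
  at the modulation rate, times 100): it measures *where* the modulation
  lies, not *how much* modulation there is relative to nothing, except for
  the very large step from zero to any positive depth. The suite asserts
  this saturation; a strictly-increasing depth response would require
  unmodulated reference energy (e.g. a noise floor) that these stimuli
  lack. On natural recordings, broadband noise and unmodulated harmonics
  provide that reference.
* **Above-Nyquist aliasing.** With the default 2-ms step the STFT route
  cannot represent modulation above 250 Hz; a 400-Hz AM stimulus aliases to
  100 Hz — the peak of the weighting window — while the auditory route
  correctly assigns it near-zero weight. The pipeline-agreement test
  computes the correlation over the full 5–400 Hz battery (capped by these
  aliased stimuli) alongside the correlation within the representable
  range, which is near-perfect. For recordings that may contain very fast
  modulation, use the auditory front end or a smaller `step`.

## Numerical choices

* **Butterworth stability.** A bandpass filter expressed as a single
  transfer-function polynomial loses precision catastrophically when the
  passband is narrow relative to the sampling rate — exactly the low-
  frequency bands of an ERB bank at 44.1 kHz. Filters are therefore
  designed in closed form (analog prototype → bandpass transform →
  bilinear, with prewarped edges) and applied as cascaded second-order
  sections, each section a stable biquad; gain is normalized to 1 at the
  digital center frequency. Filtering is forward-only (causal); the group
  delay is small relative to 200-ms fragments and is not compensated.
  Gammatone kernels span at least 10 periods of their center frequency and
  at least six envelope time constants, are normalized to unit peak
  frequency response, and the convolution output is read from the kernel's
  energy centroid onward to keep bands approximately aligned.
* **Edge clamping.** A filter's corner frequencies are clamped to
  [1 Hz, 0.97 × Nyquist]; filters whose clamped passband collapses below
  1 Hz are dropped with a warning, and a configuration losing all filters
  is an error. (The ERB rule gives bandwidths exceeding 2·cf at very low
  centers, so clamping is unavoidable there.)
* **Fragment taper.** Envelope fragments are Hann-tapered after mean
  removal. Mean removal alone only cancels DC leakage; a modulation rate
  falling between the fragment's frequency bins otherwise leaks across the
  entire modulation axis, and because that axis is ~18× longer for
  audio-rate envelopes than for STFT-band envelopes, untapered spectra
  bias the two pipelines' normalized roughness differently (up to ~2× for
  the auditory route). `taper = "none"` restores rectangular fragments.
* **Mean removal in the 2D route.** Each band's time-mean is removed
  (not just the global mean): by separability of the 2D FFT this zeroes
  exactly the temporal-DC column — the static spectral profile — whose
  leakage would otherwise dominate low modulation frequencies, and makes
  the 2D route consistent with the 1D route.
* **Degenerate inputs.** A silent fragment (zero denominator) yields `NA`
  roughness and is flagged excluded rather than raising an error; a whole
  file of silence returns a result with `summary = NA`. Fragments shorter
  than 8 columns are an error. Window sample counts round to the nearest
  integer and the FFT length equals the window length (no zero-padding), so
  STFT bin spacing is exactly `1000/window_length` Hz; the final partial
  STFT frame is dropped.
* **"log" scale.** Defined as equal spacing in log2(Hz) (semitone-like),
  the natural musical log axis.

## Problem sizes

Tests run on 0.25–1-s stimuli at 8–44.1 kHz; the pipeline-comparison
battery is 20 one-second stimuli through both pipelines; oracle checks use
16-band × 64-column random fragments against a direct O(n²) DFT (agreement
to 1e-9). The full suite completes in a few minutes on one CPU.

## Known limitations

* No perceptual data ship with the package; `evaluate_ratings()` and
  `scripts/evaluate_ratings.R` compute per-corpus Pearson correlations and
  their sign-corrected geometric mean
  (`√(xy)`, or `√((x+1)(y+1))−1` if either is negative — deliberately
  discontinuous at zero) once rated corpora are supplied.
* Linear filterbank only: no level-dependent bandwidths, hair-cell
  saturation or traveling-wave cochlear models, and no loudness dependence
  of roughness.
* Voicing is handled through an externally supplied interval mask; there is
  no internal pitch tracker.
* The unnormalized (`normalize = FALSE`) output has arbitrary units and is
  only meaningful for comparisons under identical settings.
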