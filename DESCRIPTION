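Package: roughvoc
Title: Acoustic Estimation of Voice Roughness from Temporal Modulation Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates perceived roughness of voices and other vocalizations
    from audio recordings. The sound is converted to an auditory spectrogram
    (gammatone or Butterworth filterbank followed by Hilbert envelopes) or a
    finely stepped STFT spectrogram; temporal modulation spectra are computed
    per frequency band over short fragments; and roughness is quantified as
    the weighted proportion of modulation energy in the rough range of
    modulation frequencies (about 50-200 Hz), returned as a contour over time
    and a summary value per recording. Includes synthetic-stimulus generators
    (amplitude-modulated tones, two-tone beat pairs, harmonic vowels, click
    trains), WAV input/output, psychoacoustic frequency scales (ERB, bark),
    diagnostic plots (roughness and modulation spectrograms), batch analysis,
    and utilities for comparing estimates against human ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
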