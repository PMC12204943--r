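# Brute-force DFT magnitude oracle for one envelope row: O(n^2) evaluation of
# the definition, independent of the FFT path it checks.
dft_magnitude_oracle <- function(row, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(row)
  y <- row - mean(row)
  if (taper == "hann") {
    y <- y * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  n_keep <- floor(n / 2) + 1
  vapply(seq_len(n_keep) - 1, function(k) {
    Mod(sum(y * exp(-2i * pi * k * (seq_len(n) - 1) / n)))
  }, numeric(1))
}

# Frequency of the largest mod-spectrum bin at or above f_min, averaged over
# bands (row-mean profile).
peak_mod_freq <- function(ms, f_min = 1) {
  prof <- colMeans(ms$values)
  keep <- ms$mod_freqs >= f_min
  ms$mod_freqs[keep][which.max(prof[keep])]
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / abs(expected), rel_tol)
}
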