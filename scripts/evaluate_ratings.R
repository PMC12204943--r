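#!/usr/bin/env Rscript

# Optional: compare acoustic roughness estimates against human ratings for a
# locally available corpus (audio folder + ratings CSV with columns
# id,rating). Runs both recommended configurations and reports per-corpus
# Pearson correlations and their sign-corrected geometric mean when two
# corpora are given.
#
#   Rscript scripts/evaluate_ratings.R audio1/ ratings1.csv [audio2/ ratings2.csv]

suppressPackageStartupMessages(library(roughvoc))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) %% 2 != 0 || length(args) == 0) {
  stop("usage: evaluate_ratings.R <audio_dir> <ratings_csv> [<audio_dir2> <ratings_csv2>]")
}
corpora <- split(args, rep(seq_len(length(args) / 2), each = 2))

configs <- list(STFT = roughness_config("STFT"),
                audSpec = roughness_config("audSpec"))
for (cfg_name in names(configs)) {
  rs <- vapply(corpora, function(cp) {
    batch <- run_batch(cp[1], tempfile(), config = configs[[cfg_name]])
    est <- batch$summary
    est$estimate <- est$summary_roughness_pct
    evaluate_ratings(cp[2], est)$r
  }, numeric(1))
  cat(sprintf("%s: %s\n", cfg_name,
              paste(sprintf("r%d = %.3f", seq_along(rs), rs),
                    collapse = ", ")))
  if (length(rs) == 2) {
    cat(sprintf("  geometric mean = %.3f\n", gmean_corr(rs[1], rs[2])))
  }
}
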