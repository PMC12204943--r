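#' Pearson correlation between estimates and ratings
#'
#' Standard product-moment correlation with explicit preconditions: equal
#' lengths of at least 3 and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors
#' @return correlation in \[-1, 1\]
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Sign-corrected geometric mean of two correlations
#'
#' Combines per-corpus correlations into one performance score. The plain
#' geometric mean `sqrt(x * y)` is undefined or misleading when a
#' correlation is negative, so in that case the corrected form
#' `sqrt((x + 1) * (y + 1)) - 1` is used. The geometric mean is preferred
#' over the arithmetic mean because it penalizes very low performance in one
#' corpus. Note the function is deliberately discontinuous at zero.
#'
#' @param x,y correlations in \[-1, 1\]
#' @return combined score
#' @export
#' @examples
#' gmean_corr(0.68, 0.72)
#' gmean_corr(-0.5, 0.5)   # corrected branch
gmean_corr <- function(x, y) {
  if (abs(x) > 1 || abs(y) > 1) stop("correlations must lie in [-1, 1]")
  if (x >= 0 && y >= 0) sqrt(x * y) else sqrt((x + 1) * (y + 1)) - 1
}

#' Compare roughness estimates with human ratings
#'
#' Joins a ratings table (CSV with columns `id` and `rating`) to a table of
#' acoustic estimates by stimulus id and reports the Pearson correlation.
#'
#' @param ratings a data.frame with columns `id`, `rating`, or a path to such
#'   a CSV
#' @param estimates a data.frame with columns `id`, `estimate` (e.g. the
#'   summary CSV of [run_batch()], whose `summary_roughness_pct` is accepted
#'   as the estimate column)
#' @return a list with the merged data.frame `data`, `n`, and `r`
#' @export
evaluate_ratings <- function(ratings, estimates) {
  if (is.character(ratings)) {
    ratings <- utils::read.csv(ratings, stringsAsFactors = FALSE)
  }
  if (!all(c("id", "rating") %in% names(ratings))) {
    stop("ratings must have columns 'id' and 'rating'")
  }
  if (anyDuplicated(ratings$id)) stop("duplicate stimulus ids in ratings")
  if (!"estimate" %in% names(estimates)) {
    if ("summary_roughness_pct" %in% names(estimates)) {
      estimates$estimate <- estimates$summary_roughness_pct
    } else stop("estimates must have an 'estimate' column")
  }
  m <- merge(ratings[c("id", "rating")], estimates[c("id", "estimate")],
             by = "id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("fewer than 3 matched stimuli")
  list(data = m, n = nrow(m), r = pearson(m$rating, m$estimate))
}
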