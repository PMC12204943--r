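settings_fingerprint <- function(config) {
  w <- config$weight
  parts <- c(
    sprintf("specSource=%s", config$spec_source),
    sprintf("msType=%s", config$ms_type),
    if (w$form == "rectangular") {
      sprintf("roughRange=%g:%g", w$lo, w$hi)
    } else {
      c("roughRange=NULL",
        sprintf("roughMean=%g", w$mean),
        sprintf("roughSD=%g", if (w$form == "gaussian_hz") w$sd_hz else w$sd_semitones))
    },
    "logSpec=FALSE", "logMPS=FALSE",
    sprintf("power=%d", config$stft$magnitude_exponent),
    sprintf("roughMinFreq=%g", w$rough_min_freq),
    sprintf("amRes=%g", config$fragmentation$am_res),
    if (config$spec_source == "STFT") {
      c(sprintf("windowLength=%g", config$stft$window_length),
        sprintf("step=%g", config$stft$step))
    } else {
      c(sprintf("nFilters=%d", config$filterbank$n_filters),
        sprintf("filterType=%s", config$filterbank$filter_type),
        sprintf("yScale=%s", config$filterbank$scale),
        sprintf("dynamicRange=%g", config$filterbank$dynamic_range))
    },
    sprintf("summaryStat=%s", config$summary_stat),
    sprintf("silenceThresholdDb=%g", config$silence_threshold_db)
  )
  paste(parts, collapse = ";")
}

#' Batch roughness analysis of a file or folder
#'
#' Analyzes one WAV file or every WAV file in a folder and writes two CSVs:
#' `<output>_summary.csv` with one row per file (id, fragment counts, summary
#' roughness, settings fingerprint) and `<output>_contour.csv` with one row
#' per fragment (id, start time, RMS, inclusion flag, roughness). Files are
#' processed in filename order so repeated runs produce byte-identical
#' output. Unreadable files are logged to standard error and skipped; the
#' run fails only if every file fails.
#'
#' @param input path to a WAV file or a folder of WAV files
#' @param output output path stem for the two CSVs
#' @param config a [roughness_config()]
#' @param mask_dir optional folder of per-recording voicing masks, each a CSV
#'   `start_s,end_s` named `<input stem>_mask.csv`
#' @return invisibly, a list with `summary` and `contour` data.frames and the
#'   two file paths
#' @export
run_batch <- function(input, output = "roughness", config = roughness_config(),
                      mask_dir = NULL) {
  if (!file.exists(input)) stop("input not found: ", input)
  files <- if (dir.exists(input)) {
    sort(list.files(input, pattern = "\\.wav$", ignore.case = TRUE,
                    full.names = TRUE))
  } else input
  if (length(files) == 0) stop("no WAV files in folder: ", input)

  fp <- settings_fingerprint(config)
  summary_rows <- list()
  contour_rows <- list()
  n_failed <- 0

  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    t_start <- proc.time()[["elapsed"]]
    res <- tryCatch({
      mask <- NULL
      if (!is.null(mask_dir)) {
        mf <- file.path(mask_dir, paste0(id, "_mask.csv"))
        if (file.exists(mf)) mask <- utils::read.csv(mf)
      }
      roughness(f, config = config, mask = mask)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1
      message(sprintf("[roughvoc] skipping %s: %s", f, conditionMessage(res)))
      next
    }
    message(sprintf("[roughvoc] %s: %.2f s", id,
                    proc.time()[["elapsed"]] - t_start))
    summary_rows[[id]] <- data.frame(
      id = id,
      n_fragments = length(res$fragment_roughness),
      n_included = sum(res$included),
      summary_roughness_pct = res$summary,
      settings = fp
    )
    contour_rows[[id]] <- cbind(id = id, as.data.frame(res))
  }
  if (length(summary_rows) == 0) {
    stop("all ", n_failed, " input file(s) failed to analyze")
  }

  summary_df <- do.call(rbind, summary_rows)
  contour_df <- do.call(rbind, contour_rows)
  summary_path <- paste0(output, "_summary.csv")
  contour_path <- paste0(output, "_contour.csv")
  utils::write.csv(summary_df, summary_path, row.names = FALSE)
  utils::write.csv(contour_df, contour_path, row.names = FALSE)
  invisible(list(summary = summary_df, contour = contour_df,
                 summary_path = summary_path, contour_path = contour_path))
}
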