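model_error <- function(msg) abort(msg, class = "imusleep_model_error")

#' Run the full analysis pipeline on one raw recording
#'
#' Raw IMU CSV -> feature extraction -> normalization (with the checkpoint's
#' stored parameters) -> class probabilities -> Sleep Depth Trend and
#' predicted hypnogram -> classifier-result CSV plus the multi-panel night
#' report. Outputs are written atomically (to a temporary name, renamed on
#' success), so a failing run never leaves partial result files behind.
#' Given identical inputs the result CSV is byte-identical across runs.
#'
#' @param raw_path Path to a raw IMU CSV ([read_imu_csv()] format).
#' @param model_path Path to a classifier checkpoint written by
#'   [save_model()] *with* its normalizer.
#' @param out_dir Output directory (created if missing).
#' @param config A [feature_config()].
#' @param smooth_window SDT smoothing window (odd number of epochs).
#' @param render_report Also render the night-report PNG.
#' @return Invisibly, a list with the result tibble and the paths written.
#' @export
run_pipeline <- function(raw_path, model_path, out_dir,
                         config = feature_config(), smooth_window = 5L,
                         render_report = TRUE) {
  rec <- read_imu_csv(raw_path)
  ck <- load_model(model_path)
  if (is.null(ck$normalizer)) {
    model_error("checkpoint does not contain normalizer parameters; re-save with save_model(..., normalizer = )")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fm <- extract_features(rec, config)
  nf <- apply_normalizer(fm, ck$normalizer)
  proba <- predict_proba(ck$model, nf)
  trace <- compute_sdt(proba, smooth_window)
  pred <- discretize(proba)

  result <- tibble::tibble(
    epoch = fm$epoch,
    p_wake = proba$p_wake, p_n1rem = proba$p_n1rem, p_n2n3 = proba$p_n2n3,
    pred = as.character(pred$label),
    sdt = trace$sdt_value, sdt_conf = trace$sdt_confidence,
    posture = fm$posture_code, resp_rate = fm$resp_rate,
    activity = fm$activity)

  id <- attr(rec, "recording_id")
  csv_path <- file.path(out_dir, paste0(id, "_result.csv"))
  png_path <- file.path(out_dir, paste0(id, "_report.png"))
  tmp_csv <- tempfile("result", tmpdir = out_dir, fileext = ".csv")
  tmp_png <- tempfile("report", tmpdir = out_dir, fileext = ".png")
  tryCatch({
    write_classifier_result(result, tmp_csv)
    file.rename(tmp_csv, csv_path)
    if (render_report) {
      p <- plot_night_report(fm, trace)
      ggplot2::ggsave(tmp_png, p, width = 9, height = 7, dpi = 120)
      file.rename(tmp_png, png_path)
    }
  }, error = function(e) {
    unlink(c(tmp_csv, tmp_png))
    abort(paste0("pipeline output failed for ", id, ": ", conditionMessage(e)),
          class = "imusleep_output_error")
  })
  invisible(list(result = result,
                 result_path = csv_path,
                 report_path = if (render_report) png_path else NULL))
}

#' Render a night report directly from in-sensor datalogs
#'
#' The in-sensor logging use case: the physiological panels (activity,
#' posture, respiration rate) are plotted straight from the per-epoch
#' feature log without any raw data; if per-epoch class probabilities are
#' also available (e.g. from a classifier-result CSV) the Sleep Depth Trend
#' panel is added on top. Respiration-rate spikes at `qc_valid = FALSE`
#' epochs are plotted but marked as artefacts.
#'
#' @param feature_log_path Path to a feature-log CSV ([read_feature_log()]).
#' @param probabilities_path Optional path to a CSV containing `p_wake,
#'   p_n1rem, p_n2n3` columns (a classifier-result CSV qualifies). An empty
#'   file degrades gracefully to the physiological panels.
#' @param out_path Optional PNG path; when given, the plot is saved.
#' @param smooth_window SDT smoothing window.
#' @return The ggplot object, invisibly when `out_path` is given.
#' @export
report_from_logs <- function(feature_log_path, probabilities_path = NULL,
                             out_path = NULL, smooth_window = 5L) {
  fm <- read_feature_log(feature_log_path)
  trace <- NULL
  if (!is.null(probabilities_path)) {
    df <- tryCatch(
      readr::read_csv(probabilities_path, show_col_types = FALSE, progress = FALSE),
      error = function(e) NULL)
    if (!is.null(df) && nrow(df) > 0 &&
        all(c("p_wake", "p_n1rem", "p_n2n3") %in% names(df))) {
      if (nrow(df) != nrow(fm)) {
        abort(sprintf("feature log (%d epochs) and probabilities (%d epochs) are misaligned",
                      nrow(fm), nrow(df)))
      }
      trace <- compute_sdt(df[c("p_wake", "p_n1rem", "p_n2n3")], smooth_window)
    }
  }
  p <- plot_night_report(fm, trace)
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 9, height = 7, dpi = 120)
    return(invisible(p))
  }
  p
}
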