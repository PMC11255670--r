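state_depths <- c(WAKE = 0, N1REM = 1, N2N3 = 2)

epoch_hours <- function(epoch) (epoch - 0.5) * EPOCH_SEC / 3600

#' Plot a Sleep Depth Trend with its confidence band
#'
#' @param object An `sdt_trace` from [compute_sdt()].
#' @param ... Unused.
#' @return A ggplot object: depth (0 wake, 1 light, 2 deep) over time with a
#'   shaded band of half-width `1 - confidence`.
#' @export
autoplot.sdt_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$hours <- epoch_hours(df$epoch)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$sdt_value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sdt_value - (1 - .data$sdt_confidence),
                                      ymax = .data$sdt_value + (1 - .data$sdt_confidence)),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::scale_y_continuous(breaks = 0:2, labels = c("Wake", "N1/REM", "N2/N3"),
                                limits = c(-0.1, 2.1)) +
    ggplot2::labs(x = "Time (h)", y = "Sleep depth") +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram
#'
#' @param object A [hypnogram()] (either scheme).
#' @param ... Unused.
#' @export
autoplot.hypnogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$hours <- epoch_hours(df$epoch)
  lv <- levels(object$label)
  df$y <- as.integer(df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$y)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::scale_y_continuous(breaks = seq_along(lv), labels = lv) +
    ggplot2::labs(x = "Time (h)", y = "Stage") +
    ggplot2::theme_minimal()
}

#' Plot per-epoch features over the night
#'
#' @param object A [feature_matrix()].
#' @param ... Unused.
#' @export
autoplot.feature_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$hours <- epoch_hours(df$epoch)
  long <- tidyr::pivot_longer(df, dplyr::all_of(c(CLASSIFIER_FEATURES, "posture_code")),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hours, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30", na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of per-recording cross-validation performance
#'
#' @param object A `losocv_result`.
#' @param ... Unused.
#' @export
autoplot.losocv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, dplyr::all_of(c("acc", "mcc")),
                              names_to = "metric", values_to = "value")
  long$metric <- toupper(long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Per-recording value") +
    ggplot2::theme_minimal()
}

#' Heat-map of a confusion matrix
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  pct <- row_percentages(object)
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("true", "pred", "n")
  df$pct <- as.vector(pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true, fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d\n(%.0f%%)", .data$n, .data$pct))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", na.value = "grey90") +
    ggplot2::scale_y_discrete(limits = rev(STATES3)) +
    ggplot2::labs(x = "Predicted", y = "True", fill = "Row %") +
    ggplot2::theme_minimal()
}

#' Multi-panel night report
#'
#' The standard graphical output for one night: Sleep Depth Trend with its
#' confidence band (when probabilities are available), movement activity,
#' the posture-code step trace (1 left side, 2 supine, 3 right side,
#' 4 prone, 5 head down, 6 head up), and the 30-s respiration-rate trace
#' with `qc_valid = FALSE` epochs marked — sudden rate spikes at flagged
#' epochs are artefacts of posture changes or other movements, which is why
#' the QC markers are drawn.
#'
#' @param features A [feature_matrix()].
#' @param sdt Optional `sdt_trace` aligned to the same epochs.
#' @return A ggplot object with shared time axis and free y scales.
#' @export
plot_night_report <- function(features, sdt = NULL) {
  fm <- tibble::as_tibble(features)
  if (!is.null(sdt) && nrow(sdt) != nrow(fm)) {
    abort(sprintf("feature log (%d epochs) and probabilities (%d epochs) are misaligned",
                  nrow(fm), nrow(sdt)))
  }
  hours <- epoch_hours(fm$epoch)
  panels <- c("Sleep Depth Trend", "Activity (m/s²)", "Posture code",
              "Respiration (bpm)")
  parts <- list(
    tibble::tibble(hours = hours, value = fm$activity, lo = NA_real_, hi = NA_real_,
                   qc = TRUE, panel = panels[2]),
    tibble::tibble(hours = hours, value = as.numeric(fm$posture_code),
                   lo = NA_real_, hi = NA_real_, qc = TRUE, panel = panels[3]),
    tibble::tibble(hours = hours, value = fm$resp_rate, lo = NA_real_, hi = NA_real_,
                   qc = fm$qc_valid, panel = panels[4]))
  if (!is.null(sdt)) {
    parts <- c(list(tibble::tibble(
      hours = hours, value = sdt$sdt_value,
      lo = sdt$sdt_value - (1 - sdt$sdt_confidence),
      hi = sdt$sdt_value + (1 - sdt$sdt_confidence),
      qc = TRUE, panel = panels[1])), parts)
  }
  long <- dplyr::bind_rows(parts)
  long$panel <- factor(long$panel, levels = panels)
  flagged <- long[long$panel == panels[4] & !long$qc & !is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hours, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         data = long[!is.na(long$lo), ],
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_step(data = long[long$panel == panels[3], ], colour = "grey30") +
    ggplot2::geom_line(data = long[long$panel != panels[3], ], colour = "grey20",
                       na.rm = TRUE) +
    ggplot2::geom_point(data = flagged, colour = "firebrick", shape = 4, size = 1.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(
      x = "Time since recording start (h)", y = NULL,
      caption = "Posture codes: 1 left side, 2 supine, 3 right side, 4 prone, 5 head down, 6 head up. × = qc-flagged epoch.") +
    ggplot2::theme_minimal()
}
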