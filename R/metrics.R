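as_labels3 <- function(x, what = "labels") {
  if (inherits(x, "hypnogram")) {
    if (attr(x, "scheme") != "merged3") {
      abort(sprintf("%s must use the merged 3-state scheme", what))
    }
    x <- as.character(x$label)
  }
  x <- as.character(x)
  if (!all(x %in% STATES3)) abort(sprintf("%s outside the 3-state alphabet", what))
  factor(x, levels = STATES3)
}

#' Confusion matrix of true vs predicted sleep states
#'
#' 3x3 integer counts, rows = true class, columns = predicted class.
#'
#' @param truth,pred 3-state [hypnogram()]s (or character/factor vectors) of
#'   equal length.
#' @param mask Optional logical vector; only epochs with `mask = TRUE` are
#'   counted (e.g. `qc_valid`).
#' @return A matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, mask = NULL) {
  t3 <- as_labels3(truth, "truth")
  p3 <- as_labels3(pred, "pred")
  if (length(t3) != length(p3)) {
    abort(sprintf("truth (%d epochs) and pred (%d epochs) differ in length",
                  length(t3), length(p3)))
  }
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(t3))
    t3 <- t3[mask]
    p3 <- p3[mask]
  }
  cm <- unclass(table(true = t3, pred = p3))
  storage.mode(cm) <- "integer"
  class(cm) <- "confusion_matrix"
  cm
}

#' Row-percentage view of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return A matrix of row percentages (each non-empty row sums to 100).
#' @export
row_percentages <- function(cm) {
  m <- unclass(cm)
  rs <- rowSums(m)
  out <- sweep(m, 1, ifelse(rs > 0, rs, 1), "/") * 100
  out[rs == 0, ] <- NA_real_
  out
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction of epochs on the diagonal.
#' @export
accuracy <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) abort("empty confusion matrix")
  sum(diag(m)) / total
}

#' Multiclass Matthews correlation coefficient
#'
#' The multiclass generalization
#' \deqn{MCC = (c s - \sum_k p_k t_k) / \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}
#' with \eqn{c} the diagonal sum, \eqn{s} the total, and \eqn{p_k, t_k} the
#' column and row sums. Defined as 0 when a denominator factor vanishes
#' (e.g. all predictions in one class), the chance-level value.
#'
#' @param cm A [confusion_matrix()].
#' @return A value in \[-1, 1\].
#' @export
mcc <- function(cm) {
  m <- unclass(cm)
  storage.mode(m) <- "double" # count products overflow integer range
  s <- sum(m)
  if (s == 0) abort("empty confusion matrix")
  c0 <- sum(diag(m))
  tk <- rowSums(m)
  pk <- colSums(m)
  num <- c0 * s - sum(pk * tk)
  d1 <- s^2 - sum(pk^2)
  d2 <- s^2 - sum(tk^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  num / sqrt(d1 * d2)
}

#' Per-class recall (row-wise accuracy)
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble with `state`, `n_true`, `recall`; classes absent from
#'   the truth get `recall = NA` (undefined, not zero).
#' @export
class_recalls <- function(cm) {
  m <- unclass(cm)
  rs <- rowSums(m)
  tibble::tibble(state = rownames(m),
                 n_true = as.integer(unname(rs)),
                 recall = unname(ifelse(rs > 0, diag(m) / rs, NA_real_)))
}

#' Cohort accounting over a set of scored recordings
#'
#' Exact integer epoch totals per sleep state, the overall total, and the
#' mean number of epochs per recording (rounded to the nearest integer).
#'
#' @param cohort A list of [hypnogram()]s sharing one label scheme.
#' @return A list of class `cohort_accounting` with `counts` (tibble
#'   `state`, `n_epochs`), `total_epochs`, `n_recordings`,
#'   `mean_epochs_per_recording`.
#' @export
cohort_accounting <- function(cohort) {
  stopifnot(length(cohort) >= 1)
  if (inherits(cohort, "hypnogram")) cohort <- list(cohort)
  schemes <- unique(purrr::map_chr(cohort, attr, "scheme"))
  if (length(schemes) != 1) abort("all hypnograms must share one label scheme")
  alphabet <- if (schemes == "aasm5") STATES5 else STATES3
  labels <- unlist(lapply(cohort, function(h) as.character(h$label)))
  counts <- tibble::tibble(
    state = alphabet,
    n_epochs = as.integer(table(factor(labels, levels = alphabet))))
  structure(list(counts = counts,
                 total_epochs = length(labels),
                 n_recordings = length(cohort),
                 mean_epochs_per_recording = round(length(labels) / length(cohort))),
            class = "cohort_accounting")
}

#' @export
print.cohort_accounting <- function(x, ...) {
  cat(sprintf("<cohort_accounting> %d recordings, %d epochs total (mean %d/recording)\n",
              x$n_recordings, x$total_epochs, x$mean_epochs_per_recording))
  print(x$counts)
  invisible(x)
}

#' Group summary of per-recording classifier performance
#'
#' Medians and IQRs (25th-75th percentile, linear interpolation / type 7) of
#' the per-recording accuracy and MCC values, the statistics shown as box
#' plots in classifier evaluations.
#'
#' @param per_recording A tibble with columns `acc` and `mcc` (e.g.
#'   `tidy(losocv(...))`).
#' @return A tibble with one row per metric: `median`, `q25`, `q75`, `iqr`.
#' @export
fold_summary <- function(per_recording) {
  stopifnot(nrow(per_recording) >= 1, all(c("acc", "mcc") %in% names(per_recording)))
  purrr::map_dfr(c("acc", "mcc"), function(mname) {
    x <- per_recording[[mname]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(metric = mname, median = q[2], q25 = q[1], q75 = q[3],
                   iqr = q[3] - q[1])
  })
}
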