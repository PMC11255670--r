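as_prob_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(tibble::as_tibble(p)[c("p_wake", "p_n1rem", "p_n2n3")])
  p <- unname(as.matrix(p))
  if (ncol(p) != 3) abort("expected 3-class probabilities (WAKE, N1REM, N2N3)")
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6)) {
    range_error("probability rows must be nonnegative and sum to 1 within 1e-6")
  }
  p
}

#' Sleep Depth Trend from class probabilities
#'
#' The Sleep Depth Trend (SDT) is the probability-weighted average of sleep
#' depth — WAKE = 0, N1/REM = 1, N2/N3 = 2 — per 30-s epoch, smoothed with a
#' centered moving average (the window shrinks at the edges, so every value
#' stays inside the convex hull of the raw depths it averages). The
#' confidence track is the per-epoch maximum class probability (in
#' \[1/3, 1\]), smoothed identically; it is what the shaded band in a night
#' report shows. With `smooth_window = 1` the trace equals the unsmoothed
#' weighted average exactly.
#'
#' @param p Class probabilities: a [predict_proba()] result or a 3-column
#'   matrix.
#' @param smooth_window Odd window length in epochs (default 5, i.e.
#'   2.5 min).
#' @return A tibble of class `sdt_trace` with `epoch`, `sdt_value`,
#'   `sdt_confidence`.
#' @export
compute_sdt <- function(p, smooth_window = 5L) {
  pm <- as_prob_matrix(p)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort("smooth_window must be an odd integer >= 1")
  }
  raw <- pm[, 2] + 2 * pm[, 3]
  conf <- pmax(pm[, 1], pm[, 2], pm[, 3])
  h <- (smooth_window - 1L) %/% 2L
  smooth <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i) {
      w <- max(1L, i - h):min(n, i + h)
      mean(x[w])
    }, numeric(1))
  }
  structure(tibble::tibble(epoch = seq_along(raw),
                           sdt_value = smooth(raw),
                           sdt_confidence = smooth(conf)),
            smooth_window = smooth_window,
            recording_id = attr(p, "recording_id"),
            class = c("sdt_trace", class(tibble::tibble())))
}

#' Discretize class probabilities into a 3-state hypnogram
#'
#' Arg-max per epoch; exact ties break toward the shallower state
#' (WAKE < N1REM < N2N3).
#'
#' @param p Class probabilities (see [compute_sdt()]).
#' @return A 3-state [hypnogram()].
#' @export
discretize <- function(p) {
  pm <- as_prob_matrix(p)
  idx <- max.col(pm, ties.method = "first") # columns ordered shallow -> deep
  hypnogram(STATES3[idx], scheme = "merged3",
            recording_id = attr(p, "recording_id") %||% "recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
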