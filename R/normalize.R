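#' Feature-normalization configuration
#'
#' The five classifier features are robust-z scored: centered at the median
#' and scaled by the IQR, with activity passed through `log(1 + x)` first
#' (its distribution is heavily right-skewed by movement bursts). Optionally
#' normalization statistics can be re-estimated per subject at application
#' time, which removes between-infant baseline offsets (e.g. in respiration
#' rate) without any training-data leakage.
#'
#' @param log_activity Log-transform activity before centering (default on).
#' @param per_subject Re-estimate center/scale from each recording's own
#'   valid epochs when applying (default off, matching the final model in
#'   which subject-wise normalization brought little improvement).
#' @return A list of class `normalizer_config`.
#' @export
normalizer_config <- function(log_activity = TRUE, per_subject = FALSE) {
  structure(list(log_activity = log_activity, per_subject = per_subject),
            class = "normalizer_config")
}

transform_features <- function(df, config) {
  if (config$log_activity) df$activity <- log1p(df$activity)
  df
}

#' Fit normalization parameters on training recordings
#'
#' Center (median) and scale (IQR) per feature, estimated from the pooled
#' `qc_valid` epochs of the training recordings only — test recordings must
#' never reach this function inside a cross-validation fold. A degenerate
#' (constant) feature gets scale 1 and a warning.
#'
#' @param training A [feature_matrix()] or list of them.
#' @param config A [normalizer_config()].
#' @return A `normalizer_params` object: a tibble with `feature`, `center`,
#'   `scale` plus the configuration.
#' @export
fit_normalizer <- function(training, config = normalizer_config()) {
  if (inherits(training, "feature_matrix")) training <- list(training)
  pooled <- dplyr::bind_rows(lapply(training, tibble::as_tibble))
  valid <- pooled[pooled$qc_valid, , drop = FALSE]
  if (nrow(valid) < 10) abort("need at least 10 valid epochs across training recordings")
  valid <- transform_features(valid, config)
  params <- purrr::map_dfr(CLASSIFIER_FEATURES, function(f) {
    x <- valid[[f]]
    x <- x[is.finite(x)]
    ctr <- median(x)
    scl <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
    if (!is.finite(scl) || scl == 0) {
      warn(sprintf("feature `%s` is degenerate on training data; using scale 1", f))
      scl <- 1
    }
    tibble::tibble(feature = f, center = ctr, scale = scl)
  })
  structure(list(params = params, config = config), class = "normalizer_params")
}

#' Apply (or invert) feature normalization
#'
#' Produces the classifier's input sequence: `(x - center) / scale` for each
#' of the five features. `qc_valid = FALSE` epochs get their missing
#' respiration features imputed by carrying the last valid value (backfilled
#' at the start) so the epoch grid stays aligned with the hypnogram; the QC
#' flag itself is preserved. Applying the normalizer to an already
#' normalized sequence is an error, not a silent (wrong) second scaling.
#'
#' @param fm A [feature_matrix()].
#' @param params A `normalizer_params` object from [fit_normalizer()].
#' @return A tibble with `epoch`, the five normalized features and
#'   `qc_valid`; attribute `normalized = TRUE` plus the center/scale actually
#'   used (needed by [invert_normalizer()]).
#' @export
apply_normalizer <- function(fm, params) {
  stopifnot(inherits(params, "normalizer_params"))
  if (isTRUE(attr(fm, "normalized"))) {
    abort("input is already normalized; refusing to apply the normalizer twice")
  }
  df <- tibble::as_tibble(fm)
  config <- params$config

  # carry-forward imputation of missing (qc-invalid) feature values
  for (f in CLASSIFIER_FEATURES) {
    x <- df[[f]]
    if (anyNA(x)) {
      idx <- which(!is.na(x))
      if (length(idx) == 0) {
        x[] <- 0 # no information in this recording; filled at center below
      } else {
        filled <- findInterval(seq_along(x), idx)
        filled[filled == 0] <- 1
        x <- x[idx[filled]]
      }
      df[[f]] <- x
    }
  }
  all_invalid <- !any(fm$qc_valid)
  df <- transform_features(df, config)

  p <- params$params
  if (config$per_subject && !all_invalid) {
    own <- df[fm$qc_valid, , drop = FALSE]
    p <- purrr::map_dfr(CLASSIFIER_FEATURES, function(f) {
      x <- own[[f]]
      ctr <- median(x)
      scl <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
      g <- params$params[params$params$feature == f, ]
      if (!is.finite(scl) || scl == 0) { ctr <- g$center; scl <- g$scale }
      tibble::tibble(feature = f, center = ctr, scale = scl)
    })
  }
  out <- tibble::tibble(epoch = df$epoch)
  for (f in CLASSIFIER_FEATURES) {
    row <- p[p$feature == f, ]
    out[[f]] <- (df[[f]] - row$center) / row$scale
  }
  out$qc_valid <- fm$qc_valid
  structure(out,
            recording_id = attr(fm, "recording_id"),
            normalized = TRUE,
            all_invalid = all_invalid,
            center_used = setNames(p$center, p$feature),
            scale_used = setNames(p$scale, p$feature),
            log_activity = config$log_activity,
            class = class(tibble::tibble()))
}

#' @rdname apply_normalizer
#' @param normalized Output of [apply_normalizer()].
#' @export
invert_normalizer <- function(normalized, params) {
  if (!isTRUE(attr(normalized, "normalized"))) {
    abort("input does not carry normalization metadata")
  }
  ctr <- attr(normalized, "center_used")
  scl <- attr(normalized, "scale_used")
  out <- tibble::tibble(epoch = normalized$epoch)
  for (f in CLASSIFIER_FEATURES) {
    out[[f]] <- normalized[[f]] * scl[[f]] + ctr[[f]]
  }
  if (isTRUE(attr(normalized, "log_activity"))) out$activity <- expm1(out$activity)
  out
}
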