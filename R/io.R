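# 17 significant digits: the shortest width that round-trips every double
# exactly, so written CSVs reproduce the channels bit-identically when re-read
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- NA_character_
  out[is.nan(x)] <- "NaN"
  out
}

#' Construct a validated IMU recording
#'
#' An IMU recording is a tibble with one row per sample and columns `time`
#' (POSIXct, strictly increasing, nominally 13 Hz), `ax`, `ay`, `az`
#' (acceleration, m/s², range ±8 g) and `gx`, `gy`, `gz` (angular velocity,
#' °/s, range ±500). Uniform sampling is part of the contract: gaps are an
#' error at construction time, never silently interpolated.
#'
#' @param data A data frame with columns `time, ax, ay, az, gx, gy, gz`.
#' @param recording_id Identifier string attached to the recording.
#' @param on_gap `"error"` (default) refuses streams with sampling gaps;
#'   `"split"` returns a list of gap-free recordings instead.
#' @return A tibble of class `imu_recording` (or a list of them when
#'   `on_gap = "split"` finds gaps).
#' @export
imu_recording <- function(data, recording_id = "recording", on_gap = c("error", "split")) {
  on_gap <- match.arg(on_gap)
  req <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    format_error(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[req]
  if (nrow(data) < 1) format_error("an IMU recording must contain at least one sample")
  if (!inherits(data$time, "POSIXct")) format_error("`time` must be POSIXct")
  for (ch in req[-1]) {
    if (!is.numeric(data[[ch]])) format_error(paste0("channel `", ch, "` must be numeric"))
    if (anyNA(data[[ch]])) format_error(paste0("channel `", ch, "` contains missing samples"))
  }

  nominal <- 1 / IMU_RATE_HZ
  if (nrow(data) > 1) {
    dt <- diff(as.numeric(data$time))
    if (any(dt <= 0)) format_error("timestamps are not strictly increasing")
    if (abs(median(dt) - nominal) > 0.05 * nominal) {
      format_error(sprintf(
        "median sampling interval %.5f s is not 1/13 s within 5%% tolerance", median(dt)))
    }
    gap_after <- which(dt > 1.5 * nominal)
    if (length(gap_after) > 0) {
      if (on_gap == "error") {
        format_error(sprintf(
          "sampling gap(s) detected after sample(s) %s (largest %.3f s); use on_gap = \"split\" to load segments",
          paste(head(gap_after, 5), collapse = ", "), max(dt)))
      }
      bounds <- c(0, gap_after, nrow(data))
      segs <- lapply(seq_len(length(bounds) - 1), function(i) {
        seg <- data[(bounds[i] + 1):bounds[i + 1], , drop = FALSE]
        imu_recording(seg, recording_id = sprintf("%s_seg%d", recording_id, i))
      })
      return(segs)
    }
  }

  out_acc <- abs(data$ax) > ACCEL_MAX_MS2 | abs(data$ay) > ACCEL_MAX_MS2 | abs(data$az) > ACCEL_MAX_MS2
  out_gyr <- abs(data$gx) > GYRO_MAX_DPS | abs(data$gy) > GYRO_MAX_DPS | abs(data$gz) > GYRO_MAX_DPS
  n_out <- sum(out_acc | out_gyr)
  if (n_out > 0.01 * nrow(data)) {
    range_error(sprintf(
      "%d of %d samples (%.2f%%) outside sensor range (±8 g / ±500 °/s); first offending rows: %s",
      n_out, nrow(data), 100 * n_out / nrow(data),
      paste(head(which(out_acc | out_gyr), 10), collapse = ", ")))
  }
  if (n_out > 0) {
    warn(sprintf("%d sample(s) outside sensor range were clipped to range", n_out))
    for (ch in c("ax", "ay", "az")) data[[ch]] <- pmin(pmax(data[[ch]], -ACCEL_MAX_MS2), ACCEL_MAX_MS2)
    for (ch in c("gx", "gy", "gz")) data[[ch]] <- pmin(pmax(data[[ch]], -GYRO_MAX_DPS), GYRO_MAX_DPS)
  }

  structure(data,
            recording_id = recording_id,
            sample_rate = IMU_RATE_HZ,
            start_time = data$time[1],
            class = c("imu_recording", class(tibble::tibble())))
}

#' Read / write a raw IMU stream CSV
#'
#' The on-disk format is a comma-separated UTF-8 file with header
#' `time,ax,ay,az,gx,gy,gz`; `time` is ISO-8601 with fractional seconds
#' (UTC), accelerations are m/s² and angular velocities °/s. Values are
#' written with shortest-round-trip precision so `write_imu_csv()` followed
#' by `read_imu_csv()` reproduces every channel bit-identically.
#'
#' @param path File path.
#' @param recording_id Identifier; defaults to the file name without extension.
#' @inheritParams imu_recording
#' @return `read_imu_csv()` returns an [imu_recording()]; `write_imu_csv()`
#'   returns `path` invisibly.
#' @export
read_imu_csv <- function(path, recording_id = NULL, on_gap = c("error", "split")) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  if (is.null(recording_id)) recording_id <- tools::file_path_sans_ext(basename(path))
  # channels are parsed via strtod (character -> as.numeric): the fast CSV
  # double parser can be one ulp off, which would break bit-exact round trips
  # parse noise surfaces as a clean format error from the validator below
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      time = readr::col_datetime(),
                      .default = readr::col_character())))
  for (ch in setdiff(names(df), "time")) {
    df[[ch]] <- suppressWarnings(as.numeric(df[[ch]]))
  }
  imu_recording(df, recording_id = recording_id, on_gap = on_gap)
}

#' @rdname read_imu_csv
#' @param rec An [imu_recording()].
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec) == 0) format_error("refusing to write an empty recording")
  out <- tibble::as_tibble(rec)
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) out[[ch]] <- fmt_full(out[[ch]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct a validated hypnogram
#'
#' A hypnogram is one sleep-state label per 30-s epoch. Two label schemes are
#' supported: the 5-state AASM alphabet `W, N1, N2, N3, R` (`scheme =
#' "aasm5"`) and the merged 3-state vigilance alphabet `WAKE, N1REM, N2N3`
#' (`scheme = "merged3"`) used by the classifier.
#'
#' @param labels Character vector (or factor) of per-epoch labels.
#' @param scheme `"aasm5"`, `"merged3"`, or `NULL` to infer from the labels.
#' @param recording_id Identifier string.
#' @return A tibble of class `hypnogram` with columns `epoch` and `label`.
#' @export
hypnogram <- function(labels, scheme = NULL, recording_id = "recording") {
  labels <- as.character(labels)
  if (length(labels) < 1) format_error("a hypnogram needs at least one epoch")
  if (is.null(scheme)) {
    scheme <- if (all(labels %in% STATES5)) "aasm5"
      else if (all(labels %in% STATES3)) "merged3"
      else NA_character_
  }
  alphabet <- switch(scheme, aasm5 = STATES5, merged3 = STATES3,
                     format_error("labels match neither the 5-state nor the 3-state alphabet"))
  bad <- which(!labels %in% alphabet)
  if (length(bad) > 0) {
    format_error(sprintf("unknown label token \"%s\" at epoch %d (scheme %s)",
                         labels[bad[1]], bad[1], scheme))
  }
  structure(tibble::tibble(epoch = seq_along(labels),
                           label = factor(labels, levels = alphabet)),
            recording_id = recording_id,
            scheme = scheme,
            epoch_length = EPOCH_SEC,
            class = c("hypnogram", class(tibble::tibble())))
}

#' Read / write a hypnogram file
#'
#' Accepts either the package's own CSV layout (`epoch_index,label`, one row
#' per 30-s epoch) or a bare token stream (labels separated by commas and/or
#' newlines). Unknown tokens are rejected with the token and line named.
#'
#' @param path File path.
#' @param recording_id Identifier; defaults to the file name.
#' @return `read_hypnogram()` returns a [hypnogram()].
#' @export
read_hypnogram <- function(path, recording_id = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  if (is.null(recording_id)) recording_id <- tools::file_path_sans_ext(basename(path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) format_error("empty hypnogram file")
  if (tolower(gsub("\\s", "", lines[1])) == "epoch_index,label") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            epoch_index = readr::col_integer(),
                            label = readr::col_character()))
    tokens <- df$label
    token_line <- seq_along(tokens) + 1L
  } else {
    parts <- lapply(seq_along(lines), function(i) {
      tok <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
      tok <- tok[nzchar(tok)]
      tibble::tibble(token = tok, line = i)
    })
    parts <- dplyr::bind_rows(parts)
    tokens <- parts$token
    token_line <- parts$line
  }
  known <- tokens %in% c(STATES5, STATES3)
  if (!all(known)) {
    i <- which(!known)[1]
    format_error(sprintf("unknown label token \"%s\" on line %d of %s",
                         tokens[i], token_line[i], path))
  }
  hypnogram(tokens, recording_id = recording_id)
}

#' @rdname read_hypnogram
#' @param h A [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  readr::write_csv(tibble::tibble(epoch_index = h$epoch,
                                  label = as.character(h$label)),
                   path, progress = FALSE)
  invisible(path)
}

#' Merge a 5-state AASM hypnogram into the 3-state vigilance scheme
#'
#' The classifier targets three vigilance states: `W -> WAKE`,
#' `N1, R -> N1REM` (light sleep), `N2, N3 -> N2N3` (deep sleep). Applying
#' the merge to an already-merged hypnogram is an error rather than a no-op,
#' so accidental double merges surface immediately.
#'
#' @param h A 5-state [hypnogram()].
#' @return A 3-state [hypnogram()] of the same length.
#' @export
merge_to_three_state <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (attr(h, "scheme") != "aasm5") {
    format_error("input hypnogram is already in the merged 3-state scheme")
  }
  hypnogram(unname(MERGE_MAP[as.character(h$label)]),
            scheme = "merged3",
            recording_id = attr(h, "recording_id"))
}

#' Construct a validated per-epoch feature matrix
#'
#' One row per 30-s epoch with the five classifier features (`activity` in
#' m/s²; `resp_rate` in breaths/min; `resp_amplitude` in °/s RMS;
#' `resp_variability`, a dimensionless CV; `resp_autocorr` in \[-1, 1\]),
#' the posture code (1-6) and the epoch-level quality flag `qc_valid`.
#' Respiration features may be `NA` only on `qc_valid = FALSE` epochs;
#' `activity` and `posture_code` are always present.
#'
#' @param data Data frame with columns `epoch`, the five features,
#'   `posture_code`, `qc_valid`.
#' @param recording_id Identifier string.
#' @return A tibble of class `feature_matrix`.
#' @export
feature_matrix <- function(data, recording_id = "recording") {
  req <- c("epoch", CLASSIFIER_FEATURES, "posture_code", "qc_valid")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    format_error(paste0("missing feature column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[req]
  data$qc_valid <- as.logical(data$qc_valid)
  data$posture_code <- as.integer(data$posture_code)
  # NaN (in-sensor logging artefacts) demote the epoch to qc_valid = FALSE
  has_na <- Reduce(`|`, lapply(data[CLASSIFIER_FEATURES], function(x) !is.finite(x)))
  data$qc_valid <- data$qc_valid & !has_na
  ok <- function(x, cond) all(cond(x[is.finite(x)]))
  if (!ok(data$activity, function(x) x >= 0)) range_error("activity must be >= 0")
  if (!ok(data$resp_amplitude, function(x) x >= 0)) range_error("resp_amplitude must be >= 0")
  if (!ok(data$resp_variability, function(x) x >= 0)) range_error("resp_variability must be >= 0")
  if (!ok(data$resp_autocorr, function(x) x >= -1 & x <= 1)) {
    range_error("resp_autocorr must lie in [-1, 1]")
  }
  if (!all(data$posture_code %in% 1:6)) range_error("posture_code must be in 1..6")
  if (anyNA(data$activity) || anyNA(data$posture_code)) {
    range_error("activity and posture_code must be present on every epoch")
  }
  structure(data,
            recording_id = recording_id,
            class = c("feature_matrix", class(tibble::tibble())))
}

#' Read / write a per-epoch feature log CSV
#'
#' Mirror of the in-sensor feature log: one row per 30-s epoch, columns
#' `epoch_index, activity, resp_rate, resp_amplitude, resp_variability,
#' resp_autocorr, posture_code, qc_valid`. Rows with `NaN` in a feature
#' column are kept but flagged `qc_valid = FALSE`, never dropped, so the
#' epoch grid stays aligned with the hypnogram.
#'
#' @param path File path.
#' @param recording_id Identifier; defaults to the file name.
#' @return `read_feature_log()` returns a [feature_matrix()].
#' @export
read_feature_log <- function(path, recording_id = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  if (is.null(recording_id)) recording_id <- tools::file_path_sans_ext(basename(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          epoch_index = readr::col_integer(),
                          posture_code = readr::col_integer(),
                          qc_valid = readr::col_logical(),
                          .default = readr::col_character()))
  names(df)[names(df) == "epoch_index"] <- "epoch"
  for (ch in intersect(names(df), CLASSIFIER_FEATURES)) df[[ch]] <- as.numeric(df[[ch]])
  feature_matrix(df, recording_id = recording_id)
}

#' @rdname read_feature_log
#' @param fm A [feature_matrix()].
#' @export
write_feature_log <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- tibble::as_tibble(fm)
  names(out)[names(out) == "epoch"] <- "epoch_index"
  for (ch in CLASSIFIER_FEATURES) out[[ch]] <- fmt_full(out[[ch]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a classifier result CSV
#'
#' The canonical numerical output of the pipeline: per 30-s epoch the class
#' probabilities over (WAKE, N1REM, N2N3), the arg-max predicted label, the
#' Sleep Depth Trend value and its confidence, and the physiological
#' context (posture code, respiration rate, activity).
#'
#' @param path File path.
#' @return `read_classifier_result()` returns a tibble with columns
#'   `epoch, p_wake, p_n1rem, p_n2n3, pred, sdt, sdt_conf, posture,
#'   resp_rate, activity`.
#' @export
read_classifier_result <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          epoch_index = readr::col_integer(),
                          pred = readr::col_character(),
                          posture = readr::col_integer(),
                          .default = readr::col_character()))
  names(df)[names(df) == "epoch_index"] <- "epoch"
  for (ch in setdiff(names(df), c("epoch", "pred", "posture"))) df[[ch]] <- as.numeric(df[[ch]])
  validate_classifier_result(df)
  df
}

#' @rdname read_classifier_result
#' @param res Classifier result tibble (as produced by [run_pipeline()]).
#' @export
write_classifier_result <- function(res, path) {
  validate_classifier_result(res)
  out <- tibble::as_tibble(res)
  names(out)[names(out) == "epoch"] <- "epoch_index"
  for (ch in c("p_wake", "p_n1rem", "p_n2n3", "sdt", "sdt_conf", "resp_rate", "activity")) {
    out[[ch]] <- fmt_full(out[[ch]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_classifier_result <- function(df) {
  req <- c("epoch", "p_wake", "p_n1rem", "p_n2n3", "pred", "sdt", "sdt_conf",
           "posture", "resp_rate", "activity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    format_error(paste0("missing result column(s): ", paste(missing_cols, collapse = ", ")))
  }
  p <- as.matrix(df[c("p_wake", "p_n1rem", "p_n2n3")])
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6)) {
    range_error("class probabilities must be nonnegative and sum to 1 within 1e-6")
  }
  amax <- STATES3[max.col(p, ties.method = "first")]
  if (!all(df$pred == amax)) {
    format_error("predicted label must equal the arg-max class on every epoch")
  }
  invisible(df)
}
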