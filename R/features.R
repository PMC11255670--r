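#' Feature-extraction configuration
#'
#' Tunable parameters of the per-epoch feature extractor. The respiration
#' band defaults to 0.3-1.5 Hz (18-90 breaths/min), covering infant
#' respiratory rates across 0-18 months while staying well below the 6.5 Hz
#' Nyquist limit of the 13 Hz stream.
#'
#' @param band_low_hz,band_high_hz Respiration band edges in Hz.
#' @param qc_autocorr_min Epochs whose respiratory autocorrelation peak falls
#'   below this value are flagged `qc_valid = FALSE` (quality control).
#' @param resp_dominance_min Minimum fraction of gyroscope variance inside
#'   the respiration band required to accept an axis as a respiration source.
#' @param posture_g_low,posture_g_high Accepted band (in g) for the mean
#'   acceleration norm; epochs outside are movement-dominated and carry the
#'   neighbouring posture code.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(band_low_hz = 0.3, band_high_hz = 1.5,
                           qc_autocorr_min = 0.4, resp_dominance_min = 0.5,
                           posture_g_low = 0.5, posture_g_high = 1.5) {
  stopifnot(band_low_hz > 0, band_low_hz < band_high_hz,
            band_high_hz < IMU_RATE_HZ / 2)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 qc_autocorr_min = qc_autocorr_min,
                 resp_dominance_min = resp_dominance_min,
                 posture_g_low = posture_g_low, posture_g_high = posture_g_high),
            class = "feature_config")
}

# 2nd-order Butterworth biquad (bilinear-transform / audio-EQ cookbook form),
# normalized so a0 = 1. Cascading the high-pass and low-pass sections gives
# the 4th-order recursive band-pass; filtering forward and backward makes it
# zero-phase.
rbj_biquad <- function(type = c("lowpass", "highpass"), f_hz, fs_hz) {
  type <- match.arg(type)
  w0 <- 2 * pi * f_hz / fs_hz
  alpha <- sin(w0) / (2 * (1 / sqrt(2)))
  cw <- cos(w0)
  if (type == "lowpass") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  c(b / a[1], 1, a[2] / a[1], a[3] / a[1])
}

resp_band_sos <- function(config) {
  rbind(rbj_biquad("highpass", config$band_low_hz, IMU_RATE_HZ),
        rbj_biquad("lowpass", config$band_high_hz, IMU_RATE_HZ))
}

# zero-phase band-pass of one axis; pad 60 samples (~4.6 s) by odd reflection
bandpass_axis <- function(x, sos) {
  cpp_sosfiltfilt(x - mean(x), sos, 60L)
}

as_channel_matrix <- function(x, cols) {
  if (is.data.frame(x)) x <- as.matrix(x[cols])
  x <- unname(as.matrix(x))
  if (ncol(x) != 3) format_error("expected a 3-column sample block")
  x
}

#' Movement activity of one 5-s accelerometer block
#'
#' Activity is the mean Euclidean norm of the gravity-removed acceleration
#' over a 65-sample (5-s) window; gravity is removed by subtracting the
#' window-mean vector, which is exact in static epochs and identical in
#' batch and streaming computation. The value is nonnegative and zero only
#' for a constant signal.
#'
#' @param window A 65 x 3 matrix (or data frame with `ax, ay, az`) of
#'   accelerations in m/s².
#' @return Activity in m/s².
#' @export
compute_activity <- function(window) {
  w <- as_channel_matrix(window, c("ax", "ay", "az"))
  if (nrow(w) != SAMPLES_PER_SUBEPOCH) {
    format_error(sprintf("activity window must have exactly %d samples, got %d",
                         SAMPLES_PER_SUBEPOCH, nrow(w)))
  }
  dev <- sweep(w, 2, colMeans(w))
  mean(sqrt(rowSums(dev^2)))
}

#' Movement activity of one 30-s epoch
#'
#' The 30-s activity feature is the mean of the six 5-s sub-window
#' activities ([compute_activity()]).
#'
#' @param epoch A 390 x 3 accelerometer block (m/s²).
#' @return Activity in m/s².
#' @export
epoch_activity <- function(epoch) {
  a <- as_channel_matrix(epoch, c("ax", "ay", "az"))
  if (nrow(a) != SAMPLES_PER_EPOCH) {
    format_error(sprintf("epoch must have exactly %d samples, got %d",
                         SAMPLES_PER_EPOCH, nrow(a)))
  }
  subs <- split(seq_len(SAMPLES_PER_EPOCH),
                rep(1:6, each = SAMPLES_PER_SUBEPOCH))
  mean(vapply(subs, function(i) compute_activity(a[i, , drop = FALSE]), numeric(1)))
}

#' Extract the respiration signal of one epoch from the gyroscope
#'
#' Each gyroscope axis is zero-phase band-pass filtered in the respiration
#' band; the axis retaining the largest fraction of its variance inside the
#' band is selected as the respiration source. If no axis keeps at least
#' `resp_dominance_min` of its variance in band (movement-dominated or
#' out-of-band content) or the gyroscope is flat, the epoch is flagged
#' invalid and downstream respiration features are set missing.
#'
#' @param epoch A 390 x 3 gyroscope block (°/s), or a data frame with
#'   `gx, gy, gz`.
#' @param config A [feature_config()].
#' @return A list with `signal` (390 band-passed samples), `axis`
#'   (`"x"/"y"/"z"` or `NA`), `band_fraction`, and `valid`.
#' @export
extract_respiration_signal <- function(epoch, config = feature_config()) {
  g <- as_channel_matrix(epoch, c("gx", "gy", "gz"))
  if (nrow(g) != SAMPLES_PER_EPOCH) {
    format_error(sprintf("epoch must have exactly %d samples, got %d",
                         SAMPLES_PER_EPOCH, nrow(g)))
  }
  sos <- resp_band_sos(config)
  tot <- apply(g, 2, function(x) sum((x - mean(x))^2))
  if (all(tot == 0)) {
    return(list(signal = NULL, axis = NA_character_, band_fraction = 0, valid = FALSE))
  }
  filt <- apply(g, 2, bandpass_axis, sos = sos)
  frac <- ifelse(tot > 0, colSums(filt^2) / tot, 0)
  ax <- which.max(frac)
  valid <- frac[ax] >= config$resp_dominance_min
  list(signal = if (valid) filt[, ax] else NULL,
       axis = if (valid) c("x", "y", "z")[ax] else NA_character_,
       band_fraction = unname(frac[ax]),
       valid = valid)
}

#' Respiration parameters of one epoch
#'
#' From a 390-sample band-passed respiration signal, computes the four
#' gyroscope respiration features: `resp_autocorr`, the maximal normalized
#' autocorrelation over physiological lags 0.67-3.33 s (9-43 samples at
#' 13 Hz, i.e. 18-90 breaths/min); `resp_rate = 60 / lag` of that maximum;
#' `resp_amplitude`, the RMS of the signal in °/s; and `resp_variability`,
#' the coefficient of variation of successive positive-going zero-crossing
#' intervals (0 when fewer than 3 intervals exist). The autocorrelation peak
#' doubles as the quality-control value: low values mark epochs contaminated
#' by movement or posture change.
#'
#' @param resp The band-passed signal, or `NULL` for a flagged-invalid epoch.
#' @return A one-row tibble with `resp_rate`, `resp_amplitude`,
#'   `resp_variability`, `resp_autocorr`.
#' @export
respiration_features <- function(resp) {
  if (is.null(resp) || length(resp) == 0 || !all(is.finite(resp))) {
    return(tibble::tibble(resp_rate = NA_real_, resp_amplitude = NA_real_,
                          resp_variability = NA_real_, resp_autocorr = NA_real_))
  }
  n <- length(resp)
  lags <- 9:43
  r <- vapply(lags, function(k) {
    a <- resp[1:(n - k)]
    b <- resp[(k + 1):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }, numeric(1))
  # a periodic signal peaks at its true lag and (equally) at multiples of
  # it, so the global maximum can land on a subharmonic; apply the standard
  # octave correction: step down to the half lag while its correlation
  # reaches 90 % of the current peak
  best <- which.max(r)
  repeat {
    k <- lags[best]
    halves <- unique(c(floor(k / 2), ceiling(k / 2)))
    hidx <- match(halves[halves >= min(lags)], lags)
    if (length(hidx) == 0) break
    hbest <- hidx[which.max(r[hidx])]
    if (r[best] > 0 && r[hbest] >= 0.9 * r[best]) best <- hbest else break
  }
  kmax <- lags[best]
  rate <- 60 / (kmax / IMU_RATE_HZ)
  amplitude <- sqrt(mean(resp^2))
  # positive-going zero crossings with linear sub-sample interpolation
  up <- which(resp[-n] < 0 & resp[-1] >= 0)
  tcross <- up + (-resp[up]) / (resp[up + 1] - resp[up])
  iv <- diff(tcross)
  variability <- if (length(iv) < 3) 0 else sd(iv) / mean(iv)
  tibble::tibble(resp_rate = rate, resp_amplitude = amplitude,
                 resp_variability = variability, resp_autocorr = max(r))
}

#' Classify body posture from the gravity direction
#'
#' Maps the mean acceleration vector of an epoch to one of six posture
#' codes (1 left side, 2 supine, 3 right side, 4 prone, 5 head down,
#' 6 head up) by choosing the canonical device-frame direction with the
#' smallest angle; ties break toward the lowest code. The mapping depends
#' only on direction, never on magnitude. For a full 390 x 3 epoch the mean
#' acceleration norm must lie in the configured gravity band (default
#' 0.5-1.5 g), otherwise the epoch is movement-dominated and `NA` is
#' returned so the caller can carry the neighbouring code.
#'
#' @param epoch A 390 x 3 accelerometer block, or a bare 3-vector taken as
#'   the (already averaged) acceleration direction.
#' @param config A [feature_config()].
#' @return Posture code 1-6, or `NA` for a movement-dominated epoch.
#' @export
classify_posture <- function(epoch, config = feature_config()) {
  if (is.numeric(epoch) && is.null(dim(epoch)) && length(epoch) == 3) {
    m <- epoch
  } else {
    a <- as_channel_matrix(epoch, c("ax", "ay", "az"))
    if (nrow(a) != SAMPLES_PER_EPOCH) {
      format_error(sprintf("epoch must have exactly %d samples, got %d",
                           SAMPLES_PER_EPOCH, nrow(a)))
    }
    m <- colMeans(a)
    nm <- sqrt(sum(m^2))
    if (nm < config$posture_g_low * GRAVITY_MS2 ||
        nm > config$posture_g_high * GRAVITY_MS2) {
      return(NA_integer_)
    }
  }
  nm <- sqrt(sum(m^2))
  if (nm == 0) return(NA_integer_)
  u <- m / nm
  dots <- as.matrix(POSTURE_CODES[c("ux", "uy", "uz")]) %*% u
  as.integer(which.max(dots)) # ties resolve to the lowest code
}

# all per-epoch feature computation; sees nothing outside its own 390
# samples, which is what makes streaming and batch extraction identical
epoch_features <- function(accel, gyro, config) {
  act <- epoch_activity(accel)
  rs <- extract_respiration_signal(gyro, config)
  rf <- respiration_features(rs$signal)
  list(activity = act,
       resp_rate = rf$resp_rate,
       resp_amplitude = rf$resp_amplitude,
       resp_variability = rf$resp_variability,
       resp_autocorr = rf$resp_autocorr,
       resp_valid = rs$valid,
       posture_raw = classify_posture(accel, config))
}

# carry-forward (and leading backfill) of movement-dominated posture codes,
# plus the epoch QC rule; shared verbatim by batch and streaming extraction
finalize_features <- function(rows, config, recording_id) {
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  code <- df$posture_raw
  if (all(is.na(code))) {
    code[] <- 2L # no valid gravity estimate anywhere; default supine
  } else {
    first_valid <- which(!is.na(code))[1]
    if (first_valid > 1) code[1:(first_valid - 1)] <- code[first_valid]
    for (i in seq_along(code)) if (is.na(code[i])) code[i] <- code[i - 1]
  }
  movement_dominated <- is.na(df$posture_raw)
  qc <- df$resp_valid & !movement_dominated &
    !is.na(df$resp_autocorr) & df$resp_autocorr >= config$qc_autocorr_min
  feature_matrix(tibble::tibble(
    epoch = seq_len(nrow(df)),
    activity = df$activity,
    resp_rate = df$resp_rate,
    resp_amplitude = df$resp_amplitude,
    resp_variability = df$resp_variability,
    resp_autocorr = df$resp_autocorr,
    posture_code = as.integer(code),
    qc_valid = qc
  ), recording_id = recording_id)
}

#' Extract the per-epoch feature matrix from a recording
#'
#' Applies the per-epoch operations ([epoch_activity()],
#' [extract_respiration_signal()], [respiration_features()],
#' [classify_posture()]) over contiguous non-overlapping 30-s epochs
#' (390 samples each; a trailing partial epoch is discarded). Epochs are
#' flagged `qc_valid = FALSE` when the respiratory autocorrelation falls
#' below `qc_autocorr_min`, when no gyroscope axis is respiration-dominated,
#' or when the movement-dominated posture rule fired.
#'
#' @param rec An [imu_recording()].
#' @param config A [feature_config()].
#' @return A [feature_matrix()] with `floor(n_samples / 390)` rows.
#' @export
extract_features <- function(rec, config = feature_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  a <- as_channel_matrix(rec, c("ax", "ay", "az"))
  g <- as_channel_matrix(rec, c("gx", "gy", "gz"))
  n_epochs <- nrow(a) %/% SAMPLES_PER_EPOCH
  if (n_epochs < 1) {
    format_error(sprintf("recording has %d samples; at least one full 30-s epoch (%d samples) is required",
                         nrow(a), SAMPLES_PER_EPOCH))
  }
  rows <- lapply(seq_len(n_epochs), function(e) {
    i <- ((e - 1) * SAMPLES_PER_EPOCH + 1):(e * SAMPLES_PER_EPOCH)
    epoch_features(a[i, , drop = FALSE], g[i, , drop = FALSE], config)
  })
  finalize_features(rows, config, attr(rec, "recording_id"))
}

#' Streaming (chunked) feature extraction
#'
#' Consumes the recording as an arbitrary sequence of sample blocks,
#' computing each epoch's features as soon as its 390 samples are complete —
#' the in-sensor computation model. For any chunking, the result is
#' bit-identical to [extract_features()] on the concatenated stream, because
#' every per-epoch computation sees exactly the same 390 samples and the
#' finalization step is shared.
#'
#' @param chunks A list of data frames or matrices with the six signal
#'   channels `ax, ay, az, gx, gy, gz` (a `time` column is ignored).
#' @param recording_id Identifier for the resulting matrix.
#' @param config A [feature_config()].
#' @return A [feature_matrix()].
#' @export
extract_features_streaming <- function(chunks, recording_id = "recording",
                                       config = feature_config()) {
  buf_a <- matrix(numeric(0), ncol = 3)
  buf_g <- matrix(numeric(0), ncol = 3)
  rows <- list()
  for (ch in chunks) {
    if (is.data.frame(ch)) {
      a <- as.matrix(ch[c("ax", "ay", "az")])
      g <- as.matrix(ch[c("gx", "gy", "gz")])
    } else {
      ch <- as.matrix(ch)
      a <- ch[, 1:3, drop = FALSE]
      g <- ch[, 4:6, drop = FALSE]
    }
    buf_a <- rbind(buf_a, unname(a))
    buf_g <- rbind(buf_g, unname(g))
    while (nrow(buf_a) >= SAMPLES_PER_EPOCH) {
      i <- seq_len(SAMPLES_PER_EPOCH)
      rows[[length(rows) + 1]] <-
        epoch_features(buf_a[i, , drop = FALSE], buf_g[i, , drop = FALSE], config)
      buf_a <- buf_a[-i, , drop = FALSE]
      buf_g <- buf_g[-i, , drop = FALSE]
    }
  }
  if (length(rows) == 0) {
    format_error("streamed chunks contained less than one full 30-s epoch")
  }
  finalize_features(rows, config, recording_id)
}
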