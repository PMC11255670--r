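# shared fixtures, all generated in code

t0 <- function() as.POSIXct("2026-01-01 21:00:00", tz = "UTC")

# uniform 13 Hz time base
imu_time <- function(n) t0() + (seq_len(n) - 1) / 13

# quiet supine recording: gravity on +Z, one breathing sinusoid on gyro x
# with an integer period in samples (exact autocorrelation-lag recovery)
quiet_recording <- function(minutes = 2, period_samples = 20, amp_dps = 5,
                            noise = 0, seed = 1, id = "quiet") {
  n <- round(minutes * 60 * 13)
  withr::with_seed(seed, {
    s <- sin(2 * pi * (seq_len(n) - 1) / period_samples)
    tibble::tibble(
      time = imu_time(n),
      ax = rnorm(n, 0, noise), ay = rnorm(n, 0, noise),
      az = 9.81 + rnorm(n, 0, noise),
      gx = amp_dps * s + rnorm(n, 0, noise),
      gy = rnorm(n, 0, noise), gz = rnorm(n, 0, noise)) |>
      imu_recording(recording_id = id)
  })
}

# feature-level synthetic cohort with state-conditional Gaussian features;
# used by classifier tests that do not need the raw-signal simulator
feature_cohort <- function(n_rec = 5, n_epochs = 120, sd = 0.3, seed = 1,
                           state_means = list(
                             WAKE  = c(2.0, 45, 1.0, 0.45, 0.30),
                             N1REM = c(0.3, 38, 4.0, 0.25, 0.55),
                             N2N3  = c(0.1, 30, 6.0, 0.08, 0.90)),
                           wake_weight = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_rec), function(i) {
      p <- c(wake_weight, 1, 1.5)
      states <- sample(c("WAKE", "N1REM", "N2N3"), n_epochs, TRUE, p / sum(p))
      f <- unname(t(vapply(states, function(s) state_means[[s]] + rnorm(5, 0, sd),
                           numeric(5))))
      fm <- feature_matrix(tibble::tibble(
        epoch = seq_len(n_epochs),
        activity = pmax(f[, 1], 0), resp_rate = f[, 2],
        resp_amplitude = pmax(f[, 3], 0), resp_variability = pmax(f[, 4], 0),
        resp_autocorr = pmin(pmax(f[, 5], -1), 1),
        posture_code = 2L, qc_valid = TRUE),
        recording_id = sprintf("fc%02d", i))
      list(features = fm, labels = hypnogram(states, scheme = "merged3",
                                             recording_id = sprintf("fc%02d", i)))
    })
  })
}

# split the rows of a recording into randomized contiguous chunks
random_chunks <- function(rec, n_chunks, seed) {
  withr::with_seed(seed, {
    n <- nrow(rec)
    cuts <- sort(sample(n - 1, min(n_chunks - 1, n - 1)))
    bounds <- c(0, cuts, n)
    lapply(seq_len(length(bounds) - 1), function(i) {
      tibble::as_tibble(rec)[(bounds[i] + 1):bounds[i + 1], ]
    })
  })
}

normalized_cohort <- function(cohort) {
  norm <- fit_normalizer(lapply(cohort, `[[`, "features"))
  lapply(cohort, function(r) {
    list(features = apply_normalizer(r$features, norm), labels = r$labels)
  })
}
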