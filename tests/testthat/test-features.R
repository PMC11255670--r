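test_that("activity is zero for constant signals and matches direct enumeration", {
  w <- matrix(rep(c(0, 0, 9.81), each = 65), ncol = 3)
  expect_equal(compute_activity(w), 0)

  w2 <- w
  w2[10, 1] <- w2[10, 1] + 0.65
  # oracle: per-row deviation norms from the window mean, averaged
  mu <- colMeans(w2)
  norms <- apply(w2, 1, function(r) sqrt(sum((r - mu)^2)))
  expect_equal(compute_activity(w2), mean(norms))
  expect_gt(compute_activity(w2), 0)
})

test_that("activity is homogeneous of degree 1 in the deviations", {
  withr::with_seed(5, {
    base <- matrix(rep(c(0.3, -0.2, 9.8), each = 65), ncol = 3)
    dev <- matrix(rnorm(65 * 3, 0, 0.2), ncol = 3)
    dev <- sweep(dev, 2, colMeans(dev)) # zero-mean so doubling scales deviations only
    expect_equal(compute_activity(base + 2 * dev),
                 2 * compute_activity(base + dev), tolerance = 1e-12)
  })
  expect_error(compute_activity(matrix(0, 64, 3)), class = "imusleep_format_error")
})

test_that("epoch activity is the mean of the six 5-s sub-window activities", {
  withr::with_seed(6, {
    epoch <- matrix(rnorm(390 * 3, 0, 0.5), ncol = 3)
    epoch[, 3] <- epoch[, 3] + 9.81
    subs <- vapply(1:6, function(k) {
      compute_activity(epoch[((k - 1) * 65 + 1):(k * 65), ])
    }, numeric(1))
    expect_equal(epoch_activity(epoch), mean(subs))
  })
  # one active sub-window of activity 6 among five silent ones averages to 1
  quiet <- matrix(rep(c(0, 0, 9.81), each = 390), ncol = 3)
  expect_equal(epoch_activity(quiet), 0)
  subs0 <- vapply(1:6, function(k) compute_activity(quiet[((k - 1) * 65 + 1):(k * 65), ]),
                  numeric(1))
  expect_equal(mean(c(subs0[1:5], 6)), 1)
})

test_that("respiration rate and autocorrelation are exact on integer-period sinusoids", {
  s20 <- sin(2 * pi * (0:389) / 20) # 0.65 Hz
  f20 <- respiration_features(s20)
  expect_equal(f20$resp_rate, 60 / (20 / 13)) # 39.0 bpm
  expect_gt(f20$resp_autocorr, 0.999)
  expect_lt(f20$resp_variability, 1e-9)

  s26 <- sin(2 * pi * (0:389) / 26) # 0.5 Hz
  expect_equal(respiration_features(s26)$resp_rate, 30)
})

test_that("RMS amplitude of a sinusoid is A/sqrt(2) within finite-window error", {
  A <- 3.7
  s <- A * sin(2 * pi * (0:389) / 26)
  expect_equal(respiration_features(s)$resp_amplitude, A / sqrt(2),
               tolerance = 0.02)
})

test_that("invalid respiration input yields all-missing features", {
  out <- respiration_features(NULL)
  expect_true(all(is.na(out)))
})

test_that("the respiration source axis is the band-dominant gyro axis", {
  tt <- (0:389) / 13
  g <- cbind(gx = sin(2 * pi * 0.65 * tt), gy = 0 * tt, gz = 0 * tt)
  sel <- extract_respiration_signal(g)
  expect_equal(sel$axis, "x")
  expect_true(sel$valid)

  out_of_band <- sin(2 * pi * 3 * tt)
  g3 <- cbind(out_of_band, out_of_band, out_of_band)
  expect_false(extract_respiration_signal(g3)$valid)

  expect_false(extract_respiration_signal(matrix(0, 390, 3))$valid)
})

test_that("axis recovery survives 10 dB white noise (seeded Monte Carlo)", {
  tt <- (0:389) / 13
  sig <- sin(2 * pi * 0.65 * tt)
  noise_sd <- sqrt(mean(sig^2) / 10) # SNR 10 dB
  hits <- withr::with_seed(99, {
    sum(vapply(1:100, function(i) {
      g <- cbind(sig + rnorm(390, 0, noise_sd),
                 rnorm(390, 0, noise_sd), rnorm(390, 0, noise_sd))
      identical(extract_respiration_signal(g)$axis, "x")
    }, logical(1)))
  })
  expect_gte(hits, 99)
})

test_that("posture codes follow the canonical direction table", {
  expect_equal(classify_posture(c(0, 0, 1)), 2L)  # supine
  expect_equal(classify_posture(c(-1, 0, 0)), 1L) # left side
  expect_equal(classify_posture(c(1, 0, 0)), 3L)  # right side
  expect_equal(classify_posture(c(0, 0, -1)), 4L) # prone
  expect_equal(classify_posture(c(0, -1, 0)), 5L) # head down
  expect_equal(classify_posture(c(0, 1, 0)), 6L)  # head up

  # brute-force angle oracle for an oblique vector
  v <- c(0.8, 0, 0.6)
  U <- cbind(c(-1, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 0, -1), c(0, -1, 0), c(0, 1, 0))
  angles <- acos(pmin(pmax(as.numeric(v %*% U) / sqrt(sum(v^2)), -1), 1))
  expect_equal(which.min(angles), 3)
  expect_equal(classify_posture(v), 3L)
})

test_that("posture classification is total on the sphere and magnitude-invariant", {
  withr::with_seed(17, {
    for (i in 1:200) {
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      code <- classify_posture(v)
      expect_true(code %in% 1:6)
      expect_identical(classify_posture(3.7 * v), code)
    }
  })
})

test_that("movement-dominated epochs return NA and carry neighbouring codes", {
  free_fall <- matrix(rep(c(0, 0, 0.1), each = 390), ncol = 3)
  expect_true(is.na(classify_posture(free_fall)))

  rec <- quiet_recording(minutes = 2, noise = 0.02, seed = 8)
  m <- as.matrix(tibble::as_tibble(rec)[c("ax", "ay", "az", "gx", "gy", "gz")])
  m[391:780, 1:3] <- m[391:780, 1:3] * 0.01 # second epoch in free fall
  df <- tibble::as_tibble(rec)
  df[c("ax", "ay", "az", "gx", "gy", "gz")] <- as.data.frame(m)
  fm <- extract_features(imu_recording(df))
  expect_equal(fm$posture_code[2], fm$posture_code[1]) # carried forward
  expect_false(fm$qc_valid[2])
})

test_that("feature epoch count is floor(n_samples / 390)", {
  for (minutes in c(1, 1.5)) {
    rec <- quiet_recording(minutes = minutes, seed = 2)
    extra <- tibble::as_tibble(rec)[1:100, ]
    extra$time <- max(rec$time) + (1:100) / 13
    rec2 <- imu_recording(dplyr::bind_rows(tibble::as_tibble(rec), extra))
    expect_equal(nrow(extract_features(rec2)), nrow(rec2) %/% 390)
  }
  short <- quiet_recording(minutes = 0.4)
  expect_error(extract_features(short), class = "imusleep_format_error")
})

test_that("a quiet recording yields all-valid epochs with the forced rate", {
  rec <- quiet_recording(minutes = 10, period_samples = 20, noise = 0.01, seed = 21)
  fm <- extract_features(rec)
  expect_equal(nrow(fm), 20)
  expect_true(all(fm$qc_valid))
  expect_true(all(fm$resp_rate == 39))
  expect_true(all(fm$posture_code == 2L))
})

test_that("streaming extraction equals batch extraction under any chunking", {
  rec <- quiet_recording(minutes = 5, noise = 0.3, seed = 31)
  batch <- extract_features(rec)
  one_chunk <- extract_features_streaming(list(tibble::as_tibble(rec)),
                                          recording_id = "quiet")
  expect_identical(tibble::as_tibble(one_chunk), tibble::as_tibble(batch))

  per_epoch <- random_chunks(rec, n_chunks = nrow(rec) %/% 390, seed = 1)
  mid_epoch <- list(tibble::as_tibble(rec)[1:500, ], tibble::as_tibble(rec)[501:nrow(rec), ])
  for (chunks in list(per_epoch, mid_epoch)) {
    stream <- extract_features_streaming(chunks, recording_id = "quiet")
    expect_identical(tibble::as_tibble(stream), tibble::as_tibble(batch))
  }
  for (seed in 1:20) {
    chunks <- random_chunks(rec, n_chunks = sample(2:40, 1), seed = seed)
    stream <- extract_features_streaming(chunks, recording_id = "quiet")
    expect_identical(tibble::as_tibble(stream), tibble::as_tibble(batch))
  }
})

test_that("single-sample chunks reproduce the batch features", {
  rec <- quiet_recording(minutes = 1, noise = 0.2, seed = 33)
  chunks <- lapply(seq_len(nrow(rec)), function(i) tibble::as_tibble(rec)[i, ])
  stream <- extract_features_streaming(chunks, recording_id = "quiet")
  expect_identical(tibble::as_tibble(stream),
                   tibble::as_tibble(extract_features(rec)))
})

test_that("features shift with whole-epoch time translation", {
  rec <- quiet_recording(minutes = 4, noise = 0.2, seed = 34)
  fm <- extract_features(rec)
  shifted <- tibble::as_tibble(rec)[-(1:390), ]
  fm2 <- extract_features(imu_recording(shifted))
  expect_equal(tibble::as_tibble(fm2)[-1],
               tibble::as_tibble(fm)[-1, ][-1], ignore_attr = TRUE)
})

test_that("all features are finite on valid epochs; flagged epochs keep posture/activity", {
  sc <- sim_scenario(hours = 0.5, seed = 44)
  sim <- simulate_imu(simulate_hypnogram(sc, seed = 45), sc, seed = 46)
  fm <- extract_features(sim$recording)
  expect_true(all(is.finite(fm$activity)))
  expect_true(all(fm$posture_code %in% 1:6))
  valid <- fm[fm$qc_valid, ]
  expect_true(all(is.finite(as.matrix(valid[c("resp_rate", "resp_amplitude",
                                              "resp_variability", "resp_autocorr")]))))
})
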