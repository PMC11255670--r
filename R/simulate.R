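#' Simulation scenario for synthetic infant overnight recordings
#'
#' The stated world of the simulator: a semi-Markov sleep-state sequence
#' (explicit dwell-time distributions per state, no self-transitions) driving
#' a 13 Hz IMU signal model in which respiration (a renewal process of
#' per-breath periods on the gyroscope pitch axis), movement bursts (smooth
#' pulses on both sensors) and posture (piecewise-constant gravity direction,
#' Poisson posture changes co-occurring with bursts) all depend on the
#' current state.
#'
#' The `"separable"` scenario encodes the physiological contrasts the
#' classifier features target with effect sizes large enough for stable
#' end-to-end tests: frequent large movement bursts awake (6/min), sparse
#' brief twitches in light sleep (1.5/min), near-quiescence in deep sleep
#' (0.2/min); regular deep-sleep breathing (CV 0.08) vs irregular light
#' sleep (CV 0.25); respiration rates 45/38/30 bpm. The `"hard"` scenario
#' overlaps the state-conditional distributions and triples the noise.
#'
#' @param name `"separable"` (default) or `"hard"`.
#' @param hours Recording length in hours.
#' @param n_recordings Cohort size.
#' @param seed Master seed; all randomness derives from it.
#' @param ... Named overrides of any scenario field.
#' @return A list of class `sim_scenario`. Fields are vectors over the
#'   states (WAKE, N1REM, N2N3) where state-dependent.
#' @export
sim_scenario <- function(name = c("separable", "hard"), hours = 8,
                         n_recordings = 12, seed = 1L, ...) {
  name <- match.arg(name)
  sc <- list(
    name = name,
    states = STATES3,
    dwell_mean_min = c(WAKE = 5, N1REM = 12, N2N3 = 20),
    dwell_sd_min = c(WAKE = 3, N1REM = 6, N2N3 = 8),
    # rows = from, cols = to; diagonal forced to zero
    transitions = matrix(c(0, 1, 0,
                           0.3, 0, 0.7,
                           0.2, 0.8, 0), nrow = 3, byrow = TRUE,
                         dimnames = list(STATES3, STATES3)),
    resp_rate_bpm = c(WAKE = 45, N1REM = 38, N2N3 = 30),
    breath_cv = c(WAKE = 0.30, N1REM = 0.25, N2N3 = 0.08),
    resp_amplitude_dps = c(WAKE = 2, N1REM = 5, N2N3 = 8),
    burst_rate_per_min = c(WAKE = 6, N1REM = 1.5, N2N3 = 0.2),
    burst_amp_ms2 = c(WAKE = 2.0, N1REM = 0.8, N2N3 = 0.5),
    burst_dur_s = c(WAKE = 1.5, N1REM = 0.7, N2N3 = 0.7),
    posture_changes_per_hr = 1,
    accel_noise_sd = 0.05,
    gyro_noise_sd = 0.5,
    between_subject_rate_sd = 2,
    hours = hours,
    n_recordings = as.integer(n_recordings),
    seed = as.integer(seed))
  if (name == "hard") {
    sc$resp_rate_bpm <- c(WAKE = 40, N1REM = 37, N2N3 = 34)
    sc$breath_cv <- c(WAKE = 0.25, N1REM = 0.22, N2N3 = 0.15)
    sc$resp_amplitude_dps <- c(WAKE = 3, N1REM = 4, N2N3 = 5)
    sc$burst_rate_per_min <- c(WAKE = 3, N1REM = 1.5, N2N3 = 0.8)
    sc$burst_amp_ms2 <- c(WAKE = 1.2, N1REM = 0.8, N2N3 = 0.6)
    sc$accel_noise_sd <- 0.15
    sc$gyro_noise_sd <- 1.5
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown) > 0) abort(paste0("unknown scenario field(s): ", paste(unknown, collapse = ", ")))
  sc[names(dots)] <- dots
  stopifnot(all(sc$dwell_mean_min > 0), all(sc$dwell_sd_min >= 0),
            all(sc$resp_rate_bpm >= 18), all(sc$resp_rate_bpm <= 90),
            all(sc$burst_rate_per_min >= 0), sc$accel_noise_sd >= 0,
            sc$gyro_noise_sd >= 0, sc$hours > 0, sc$n_recordings >= 1,
            all(diag(sc$transitions) == 0),
            all(abs(rowSums(sc$transitions) - 1) < 1e-9))
  structure(sc, class = "sim_scenario")
}

# lognormal parameters matching a target mean/sd on the natural scale
lognorm_pars <- function(m, s) {
  m <- unname(m)
  s <- unname(s)
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a ground-truth 3-state hypnogram
#'
#' Semi-Markov generation: dwell times are drawn per state from a truncated
#' log-normal (moment-matched to the scenario's mean/SD in minutes, clamped
#' to 0.5-120 min), rounded to whole 30-s epochs (at least one), and states
#' transition by the scenario's weights with no self-transitions. The night
#' starts awake and is truncated at the configured recording length.
#'
#' @param sc A [sim_scenario()].
#' @param seed Seed (defaults to the scenario master seed).
#' @param recording_id Identifier.
#' @return A 3-state [hypnogram()] with `hours * 120` epochs.
#' @export
simulate_hypnogram <- function(sc, seed = sc$seed, recording_id = "sim") {
  stopifnot(inherits(sc, "sim_scenario"))
  n_epochs <- round(sc$hours * 3600 / EPOCH_SEC)
  withr::with_seed(seed, {
    labels <- character(0)
    state <- "WAKE"
    while (length(labels) < n_epochs) {
      lp <- lognorm_pars(sc$dwell_mean_min[state], max(sc$dwell_sd_min[state], 1e-6))
      dwell_min <- min(max(rlnorm(1, lp["meanlog"], lp["sdlog"]), 0.5), 120)
      n_ep <- max(1L, as.integer(round(dwell_min * 60 / EPOCH_SEC)))
      labels <- c(labels, rep(state, n_ep))
      state <- sample(sc$states, 1, prob = sc$transitions[state, ])
    }
    hypnogram(labels[seq_len(n_epochs)], scheme = "merged3", recording_id = recording_id)
  })
}

# smooth Gaussian pulse of given amplitude/duration along a direction;
# returns the affected sample indices and the additive 3-channel delta so the
# caller can update its matrices in place (avoids copying whole-night arrays)
pulse_delta <- function(t, t0, amp, dur, direction) {
  sigma <- dur / 4
  lo <- max(1L, findInterval(t0 - 3 * sigma, t))
  hi <- min(length(t), findInterval(t0 + 3 * sigma, t) + 1L)
  if (hi < lo) return(NULL)
  idx <- lo:hi
  pulse <- amp * exp(-((t[idx] - t0)^2) / (2 * sigma^2))
  list(idx = idx, delta = outer(pulse, direction))
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate a raw IMU stream for a given hypnogram
#'
#' Builds the 13 Hz 6-channel stream: the accelerometer sees the gravity
#' vector of the current posture plus state-dependent movement bursts and
#' white noise; the gyroscope sees the respiration oscillation (per-breath
#' period renewal process with the state's rate and interval CV, on the
#' pitch axis of abdominal breathing) plus burst-coupled rotation and noise.
#' Posture changes arrive as a Poisson process and co-occur with a large
#' burst (the "turn" artefact). All channels are clipped to sensor range
#' (±8 g, ±500 °/s) and clipped samples are counted in the ground truth.
#'
#' @param h A 3-state [hypnogram()].
#' @param sc A [sim_scenario()].
#' @param seed Seed.
#' @param resp_rate_offset Subject-level respiration-rate offset in
#'   breaths/min (drawn by [simulate_cohort()]).
#' @param start_time Recording start (POSIXct, UTC).
#' @return A list with `recording` (an [imu_recording()]) and `truth`
#'   (per-epoch state/posture/turn table, breath times, burst times,
#'   clipped-sample count).
#' @export
simulate_imu <- function(h, sc, seed = sc$seed, resp_rate_offset = 0,
                         start_time = as.POSIXct("2026-01-01 19:00:00", tz = "UTC")) {
  stopifnot(inherits(h, "hypnogram"), attr(h, "scheme") == "merged3",
            inherits(sc, "sim_scenario"))
  n_epochs <- nrow(h)
  n <- n_epochs * SAMPLES_PER_EPOCH
  dt <- 1 / IMU_RATE_HZ
  t <- (seq_len(n) - 1) * dt
  total_s <- n * dt
  state_i <- rep(match(as.character(h$label), STATES3), each = SAMPLES_PER_EPOCH)

  withr::with_seed(seed, {
    # --- posture: piecewise constant codes, Poisson change times -----------
    n_turn <- rpois(1, sc$posture_changes_per_hr * total_s / 3600)
    turn_times <- sort(runif(n_turn, 0, total_s))
    code_weights <- c(0.3, 0.3, 0.3, 0.22, 0.04, 0.04)
    codes <- integer(n_turn + 1)
    codes[1] <- 2L # put down supine
    for (k in seq_len(n_turn)) {
      cand <- setdiff(1:6, codes[k])
      codes[k + 1] <- sample(cand, 1, prob = code_weights[cand])
    }
    seg <- findInterval(t, turn_times) + 1L
    U <- as.matrix(POSTURE_CODES[c("ux", "uy", "uz")])
    accel <- GRAVITY_MS2 * U[codes[seg], , drop = FALSE]
    gyro <- matrix(0, nrow = n, ncol = 3)

    # --- movement bursts: state-dependent Poisson, thinned -----------------
    max_rate <- max(sc$burst_rate_per_min)
    n_cand <- rpois(1, max_rate * total_s / 60)
    cand_t <- sort(runif(n_cand, 0, total_s))
    cand_state <- state_i[pmin(n, floor(cand_t / dt) + 1L)]
    keep <- runif(n_cand) < sc$burst_rate_per_min[cand_state] / max_rate
    burst_t <- cand_t[keep]
    burst_state <- cand_state[keep]
    for (k in seq_along(burst_t)) {
      s <- burst_state[k]
      amp <- sc$burst_amp_ms2[s] * runif(1, 0.6, 1.4)
      dur <- sc$burst_dur_s[s] * runif(1, 0.7, 1.3)
      pa <- pulse_delta(t, burst_t[k], amp, dur, random_unit())
      if (!is.null(pa)) accel[pa$idx, ] <- accel[pa$idx, ] + pa$delta
      pg <- pulse_delta(t, burst_t[k], amp * 40, dur, random_unit())
      if (!is.null(pg)) gyro[pg$idx, ] <- gyro[pg$idx, ] + pg$delta
    }
    # posture turns co-occur with a large burst
    for (tt in turn_times) {
      pa <- pulse_delta(t, tt, 1.5, 2, random_unit())
      if (!is.null(pa)) accel[pa$idx, ] <- accel[pa$idx, ] + pa$delta
      pg <- pulse_delta(t, tt, 80, 2, random_unit())
      if (!is.null(pg)) gyro[pg$idx, ] <- gyro[pg$idx, ] + pg$delta
    }

    # --- respiration: renewal process of per-breath periods ----------------
    rate_bpm <- pmin(pmax(sc$resp_rate_bpm + resp_rate_offset, 18), 90)
    starts <- numeric(0)
    periods <- numeric(0)
    b <- 0
    while (b < total_s) {
      s <- state_i[min(n, floor(b / dt) + 1L)]
      m <- 60 / rate_bpm[s]
      cv <- max(sc$breath_cv[s], 1e-3)
      shape <- 1 / cv^2
      per <- rgamma(1, shape = shape, scale = m / shape)
      per <- min(max(per, 60 / 90), 60 / 18) # keep within the physiological band
      starts <- c(starts, b)
      periods <- c(periods, per)
      b <- b + per
    }
    bi <- findInterval(t, starts)
    phase <- (t - starts[bi]) / periods[bi]
    resp <- sc$resp_amplitude_dps[state_i] * sin(2 * pi * phase)
    gyro[, 1] <- gyro[, 1] + resp # rotation about the mediolateral (pitch) axis

    # --- noise and sensor-range clipping -----------------------------------
    accel <- accel + matrix(rnorm(3 * n, 0, sc$accel_noise_sd), ncol = 3)
    gyro <- gyro + matrix(rnorm(3 * n, 0, sc$gyro_noise_sd), ncol = 3)
    n_clipped <- sum(abs(accel) > ACCEL_MAX_MS2) + sum(abs(gyro) > GYRO_MAX_DPS)
    accel <- pmin(pmax(accel, -ACCEL_MAX_MS2), ACCEL_MAX_MS2)
    gyro <- pmin(pmax(gyro, -GYRO_MAX_DPS), GYRO_MAX_DPS)

    rec <- imu_recording(
      tibble::tibble(time = start_time + t,
                     ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                     gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]),
      recording_id = attr(h, "recording_id"))

    mid <- (seq_len(n_epochs) - 0.5) * EPOCH_SEC
    turn_epoch <- unique(pmin(n_epochs, floor(turn_times / EPOCH_SEC) + 1L))
    truth_epochs <- tibble::tibble(
      epoch = seq_len(n_epochs),
      state = as.character(h$label),
      posture_code = codes[findInterval(mid, turn_times) + 1L],
      turn = seq_len(n_epochs) %in% turn_epoch)
    list(recording = rec,
         truth = structure(list(epochs = truth_epochs,
                                breath_times = starts,
                                burst_times = burst_t,
                                turn_times = turn_times,
                                n_clipped = n_clipped,
                                clipped_fraction = n_clipped / (6 * n)),
                           class = "sim_ground_truth"))
  })
}

#' Simulate a seeded cohort of overnight recordings
#'
#' Per-recording seeds are derived deterministically from the master seed,
#' and each subject receives a respiration-rate offset drawn from the
#' between-subject SD, creating realistic inter-infant variation for
#' leave-one-subject-out evaluation.
#'
#' @param sc A [sim_scenario()].
#' @return A list with one element per recording: `recording_id`,
#'   `recording`, `hypnogram`, `truth`, `resp_rate_offset`.
#' @export
simulate_cohort <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  offsets <- withr::with_seed(sc$seed, rnorm(sc$n_recordings, 0, sc$between_subject_rate_sd))
  lapply(seq_len(sc$n_recordings), function(i) {
    id <- sprintf("sim%02d", i)
    h <- simulate_hypnogram(sc, seed = fold_seed(sc$seed, i), recording_id = id)
    sim <- simulate_imu(h, sc, seed = fold_seed(sc$seed, i + sc$n_recordings),
                        resp_rate_offset = offsets[i])
    list(recording_id = id, recording = sim$recording, hypnogram = h,
         truth = sim$truth, resp_rate_offset = offsets[i])
  })
}
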