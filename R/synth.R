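#' Synthetic session generation
#'
#' The generators emulate exactly the statistical structure the decoding
#' pipeline assumes, so every downstream stage can be exercised end-to-end
#' without recorded data: a gait-modulated IMU heading staircase with
#' sigmoidal turns of +/-45 degrees, and EEG whose samples are draws from a
#' class-dependent 27-channel spatial covariance (monotonous walk everywhere,
#' switching to the intent covariance in the window preceding each turn),
#' contaminated with EOG-mixed ocular artifacts, slow drift and sporadic
#' high-amplitude bursts for the artifact filters to remove.
#'
#' @name synthetic-data
NULL

with_seed_ti <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a pair of SPD matrices at a controlled Riemannian distance
#'
#' The first matrix is a random SPD matrix; the second is obtained by moving
#' along a random geodesic direction, so that the affine-invariant distance
#' between the two is exactly `separation`.
#'
#' @param dim Matrix dimension (>= 2).
#' @param separation Target AIRM distance (>= 0); 0 returns identical
#'   matrices.
#' @param seed Optional RNG seed.
#' @return A list with SPD matrices `a` and `b`.
#' @export
make_spd_pair <- function(dim, separation, seed = NULL) {
  if (dim < 2) abort("dim must be >= 2.")
  if (separation < 0) abort("separation must be >= 0.")
  with_seed_ti(seed, {
    q <- qr.Q(qr(matrix(rnorm(dim^2), dim)))
    a <- q %*% (runif(dim, 0.5, 2) * t(q))
    a <- (a + t(a)) / 2
    s <- matrix(rnorm(dim^2), dim)
    s <- (s + t(s)) / 2
    s <- s / norm(s, "F")
    sa <- spd_sqrtm(a)
    b <- sa %*% spd_expm(separation * s) %*% sa
    list(a = a, b = (b + t(b)) / 2)
  })
}

#' IMU generator parameters
#'
#' Defaults mirror the recording protocol: roughly eight spontaneous turns
#' per trial at about 45 degrees, walking segments of 8-10 s between turns,
#' a 15 s standing basal prefix, gait sway at cadence frequency, and mild
#' sensor noise.
#'
#' @param n_turns Turns per trial.
#' @param turn_angle_deg Magnitude of each turn (> 0).
#' @param turn_directions `"alternate"`, or a character vector of
#'   `"left"`/`"right"` per turn, or `"random"`.
#' @param turn_sharpness_s 10-90% rise time of the sigmoidal turn.
#' @param gait_sway_amp_deg Amplitude of the sinusoidal heading sway while
#'   walking.
#' @param gait_freq_hz Sway (cadence) frequency.
#' @param sensor_noise_deg Standard deviation of white heading noise.
#' @param walk_seg_len_s Range (min, max) of walking-segment length between
#'   turns; the minimum must be >= 6 so valid repetitions exist.
#' @param basal_s Standing basal prefix duration.
#' @param third_step_delay_s Time after a segment starts at which steady
#'   walking (the "third step") is marked.
#' @param fs IMU sampling rate.
#' @param seed Optional RNG seed.
#' @export
imu_gen_params <- function(n_turns = 8, turn_angle_deg = 45,
                           turn_directions = "alternate",
                           turn_sharpness_s = 0.6,
                           gait_sway_amp_deg = 2, gait_freq_hz = 0.9,
                           sensor_noise_deg = 0.3,
                           walk_seg_len_s = c(8, 10),
                           basal_s = 15, third_step_delay_s = 2,
                           fs = 50, seed = NULL) {
  if (turn_angle_deg <= 0) abort("turn_angle_deg must be > 0.")
  if (walk_seg_len_s[1] < 6)
    abort("walk_seg_len_s minimum must be >= 6 s so repetitions are valid.")
  as.list(environment())
}

#' Generate one trial's IMU trace
#'
#' @param params From [imu_gen_params()].
#' @return List with `imu` (an [imu_trace()]), `ground_truth` (tibble:
#'   `turn_time_s`, `direction`), `third_step_marks`, `basal_end` and
#'   `duration_s`.
#' @rdname synthetic-data
#' @export
gen_imu_trial <- function(params = imu_gen_params()) {
  with_seed_ti(params$seed, {
    segs <- runif(params$n_turns, params$walk_seg_len_s[1],
                  params$walk_seg_len_s[2])
    turn_times <- params$basal_s + cumsum(segs)
    dirs <- params$turn_directions
    if (identical(dirs, "alternate")) {
      start <- sample(c("left", "right"), 1)
      dirs <- rep(c(start, setdiff(c("left", "right"), start)),
                  length.out = params$n_turns)
    } else if (identical(dirs, "random")) {
      dirs <- sample(c("left", "right"), params$n_turns, replace = TRUE)
    }
    stopifnot(length(dirs) == params$n_turns)
    sign_d <- ifelse(dirs == "right", 1, -1)

    dur <- turn_times[params$n_turns] + 3
    t <- seq(0, dur, by = 1 / params$fs)
    # logistic steps: scale chosen so the 10-90% rise takes turn_sharpness_s.
    # The ground-truth turn time marks the turn onset (the last instant of
    # monotonous heading), so the sigmoid midpoint sits half a rise time
    # later -- matching the curvature-onset semantics of the detector.
    sc <- params$turn_sharpness_s / (2 * log(9))
    heading <- rep(0, length(t))
    for (k in seq_len(params$n_turns))
      heading <- heading + sign_d[k] * params$turn_angle_deg /
        (1 + exp(-(t - turn_times[k] - params$turn_sharpness_s / 2) / sc))
    walking <- t >= params$basal_s
    sway <- params$gait_sway_amp_deg *
      sin(2 * pi * params$gait_freq_hz * t) * walking
    noise <- rnorm(length(t), 0, params$sensor_noise_deg)
    ang <- (heading + sway + noise) * pi / 180
    marks <- c(params$basal_s,
               turn_times[-params$n_turns]) + params$third_step_delay_s
    list(imu = imu_trace(sin(ang), cos(ang), fs = params$fs, t0 = 0),
         ground_truth = tibble::tibble(turn_time_s = turn_times,
                                       direction = dirs),
         third_step_marks = marks,
         basal_end = params$basal_s,
         duration_s = dur)
  })
}

#' EEG generator parameters
#'
#' `cov_walk`/`cov_intent` default to a random SPD pair at AIRM separation
#' 1.5 scaled to ~10 microvolt channel RMS, which puts the downstream
#' classifiers in a realistic (clearly above chance, below ceiling)
#' operating range.
#'
#' @param cov_walk,cov_intent 27x27 SPD class covariances (microvolts^2).
#' @param separation AIRM separation used when the pair is generated
#'   internally.
#' @param intent_onset_s The intent covariance applies from this long before
#'   each turn (>= 1.4 s, the earliest extent of the intent window).
#' @param band_of_effect Optional [band_spec()]: embed the class structure in
#'   a band-limited carrier instead of broadband iid draws.
#' @param eog_mixing 27x4 artifact propagation gains; defaults decay from
#'   frontal to parietal rows.
#' @param drift_amp_uv Slow (0.1 Hz) drift amplitude.
#' @param blink_rate_per_min,saccade_rate_per_min Ocular event rates.
#' @param burst_rate_per_min Rate of sporadic high-amplitude bursts.
#' @param burst_amp_uv,burst_len_s Burst amplitude and duration.
#' @param scale_uv Channel RMS scale applied to the unit-scale covariances.
#' @param fs EEG sampling rate.
#' @param seed Optional RNG seed.
#' @export
eeg_gen_params <- function(cov_walk = NULL, cov_intent = NULL,
                           separation = 1.5,
                           intent_onset_s = 1.4,
                           band_of_effect = NULL,
                           eog_mixing = NULL,
                           drift_amp_uv = 0,
                           blink_rate_per_min = 8,
                           saccade_rate_per_min = 10,
                           burst_rate_per_min = 0,
                           burst_amp_uv = 300, burst_len_s = 0.5,
                           scale_uv = 10, fs = 500, seed = NULL) {
  if (is.null(cov_walk) || is.null(cov_intent)) {
    pair <- make_spd_pair(27, separation, seed = seed)
    cov_walk <- pair$a * scale_uv^2
    cov_intent <- pair$b * scale_uv^2
  }
  assert_spd(cov_walk, "cov_walk"); assert_spd(cov_intent, "cov_intent")
  if (intent_onset_s < 1.4)
    abort("intent_onset_s must cover the intent window (>= 1.4 s).")
  if (is.null(eog_mixing)) eog_mixing <- default_eog_mixing()
  as.list(environment())[setdiff(ls(environment()), c("pair"))]
}

# Artifact propagation gains decaying from frontal to parietal electrodes;
# columns follow the EOG order HR, HL, VU, VD.
default_eog_mixing <- function() {
  labs <- eeg_channel_names()
  row_gain <- vapply(labs, function(l) {
    if (grepl("^F[34Z]", l)) 0.15
    else if (grepl("^FC", l)) 0.10
    else if (grepl("^C[P]", l)) 0.03
    else if (grepl("^C", l)) 0.06
    else 0.015
  }, numeric(1))
  m <- outer(row_gain, c(0.5, -0.5, 1.0, -0.6))
  dimnames(m) <- list(labs, eog_channel_names())
  m
}

#' Generate one trial's EEG and EOG recordings
#'
#' @param params From [eeg_gen_params()].
#' @param imu_gen Result of [gen_imu_trial()] for the same trial.
#' @return List with `eeg` and `eog` [recording()]s and the augmented
#'   `ground_truth` (adds `intent_onset_s` per turn and attribute-free burst
#'   times in `burst_times_s`).
#' @rdname synthetic-data
#' @export
gen_eeg_trial <- function(params, imu_gen) {
  with_seed_ti(params$seed, {
    fs <- params$fs
    n <- round(imu_gen$duration_s * fs) + 1L
    t <- (seq_len(n) - 1) / fs
    turns <- imu_gen$ground_truth$turn_time_s

    intent <- rep(FALSE, n)
    for (tt in turns)
      intent[t >= tt - params$intent_onset_s & t <= tt] <- TRUE

    l_walk <- t(chol(params$cov_walk))
    l_int <- t(chol(params$cov_intent))
    z <- matrix(rnorm(n * 27), n, 27)
    if (!is.null(params$band_of_effect)) {
      carrier <- recording(z, fs = fs)
      z <- bandpass(carrier, params$band_of_effect)$samples
      z <- z / sd(z)   # restore unit scale after band restriction
    }
    eeg <- matrix(0, n, 27)
    eeg[!intent, ] <- z[!intent, , drop = FALSE] %*% t(l_walk)
    eeg[intent, ] <- z[intent, , drop = FALSE] %*% t(l_int)

    # ocular activity on the EOG channels, mixed into the EEG
    eog <- matrix(rnorm(n * 4, 0, 2), n, 4,
                  dimnames = list(NULL, eog_channel_names()))
    n_blink <- rpois(1, params$blink_rate_per_min * imu_gen$duration_s / 60)
    if (n_blink) for (bt in runif(n_blink, 0, imu_gen$duration_s)) {
      idx <- which(t >= bt & t < bt + 0.2)
      lobe <- 150 * sin(pi * seq_along(idx) / length(idx))^2
      eog[idx, "VU"] <- eog[idx, "VU"] + lobe
      eog[idx, "VD"] <- eog[idx, "VD"] - 0.3 * lobe
    }
    n_sac <- rpois(1, params$saccade_rate_per_min * imu_gen$duration_s / 60)
    if (n_sac) for (st in runif(n_sac, 0, imu_gen$duration_s)) {
      step <- 60 * sample(c(-1, 1), 1)
      idx <- t >= st & t < st + 0.8
      eog[idx, "HR"] <- eog[idx, "HR"] + step
      eog[idx, "HL"] <- eog[idx, "HL"] - step
    }
    eeg <- eeg + eog %*% t(params$eog_mixing)

    if (params$drift_amp_uv > 0) {
      ph <- runif(27, 0, 2 * pi)
      drift <- params$drift_amp_uv *
        sin(outer(2 * pi * 0.1 * t, rep(1, 27)) + rep(ph, each = n))
      eeg <- eeg + drift
    }

    burst_times <- numeric(0)
    n_burst <- rpois(1, params$burst_rate_per_min * imu_gen$duration_s / 60)
    if (n_burst) {
      burst_times <- runif(n_burst, 1, imu_gen$duration_s - 1)
      for (bt in burst_times) {
        idx <- which(t >= bt & t < bt + params$burst_len_s)
        chans <- sample(27, 3)
        env <- sin(pi * seq_along(idx) / length(idx))^2
        for (ch in chans)
          eeg[idx, ch] <- eeg[idx, ch] +
            params$burst_amp_uv * env * rnorm(length(idx), 0, 1)
      }
    }

    gt <- imu_gen$ground_truth
    gt$intent_onset_s <- gt$turn_time_s - params$intent_onset_s
    list(eeg = recording(eeg, fs = fs, labels = eeg_channel_names(), t0 = 0),
         eog = recording(eog, fs = fs, labels = eog_channel_names(), t0 = 0),
         ground_truth = gt,
         burst_times_s = burst_times)
  })
}

#' Generate a full synthetic session
#'
#' Produces the session the recording protocol prescribes: a 60 s
#' artifact-free standing baseline (walk-class statistics) for ASR
#' calibration, then `n_trials` trials each with a 15 s basal prefix and
#' about eight spontaneous turns, with ground truth attached to every trial.
#'
#' @param imu_params,eeg_params Parameter lists; trial-specific seeds are
#'   derived from `seed`.
#' @param n_trials Number of trials (>= 1).
#' @param seed Session seed.
#' @param subject_id Identifier.
#' @return A [session()].
#' @rdname synthetic-data
#' @export
gen_session <- function(imu_params = imu_gen_params(),
                        eeg_params = eeg_gen_params(seed = seed),
                        n_trials = 10, seed = 1, subject_id = "SYN1") {
  if (n_trials < 1) abort("n_trials must be >= 1.")
  baseline <- with_seed_ti((seed * 1000 + 7) %% 2147483647, {
    n <- 60 * eeg_params$fs
    z <- matrix(rnorm(n * 27), n, 27)
    recording(z %*% chol(eeg_params$cov_walk),
              fs = eeg_params$fs, labels = eeg_channel_names())
  })
  trials <- lapply(seq_len(n_trials), function(i) {
    ip <- imu_params; ip$seed <- (seed * 131L + i) %% 2147483647L
    ep <- eeg_params; ep$seed <- (seed * 131L + i + 500L) %% 2147483647L
    im <- gen_imu_trial(ip)
    ee <- gen_eeg_trial(ep, im)
    # trim streams to a common wall-clock length
    n_imu <- length(im$imu$xz)
    n_eeg <- min(nrow(ee$eeg$samples), n_imu * 10L)
    n_eeg <- (n_eeg %/% 10L) * 10L
    trial(
      eeg = recording(ee$eeg$samples[seq_len(n_eeg), , drop = FALSE],
                      fs = ep$fs, labels = eeg_channel_names()),
      eog = recording(ee$eog$samples[seq_len(n_eeg), , drop = FALSE],
                      fs = ep$fs, labels = eog_channel_names()),
      imu = imu_trace(im$imu$xz[seq_len(n_eeg %/% 10L)],
                      im$imu$yz[seq_len(n_eeg %/% 10L)], fs = ip$fs),
      basal_end = im$basal_end,
      third_step_marks = im$third_step_marks,
      ground_truth = ee$ground_truth)
  })
  session(trials, baseline, subject_id = subject_id)
}
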