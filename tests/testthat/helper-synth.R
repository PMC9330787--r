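# Shared fixtures, all generated in code.

# Covariance epochs sampled from a class covariance: each epoch is the SCM
# of `n_samp` iid multivariate-normal draws.
sample_cov_epochs <- function(sigma, n_epochs, n_samp = 120) {
  lapply(seq_len(n_epochs), function(i)
    scm(MASS::mvrnorm(n_samp, rep(0, nrow(sigma)), sigma)))
}

# A labeled epoch tibble for two classes at a given AIRM separation.
two_class_epochs <- function(dim = 8, separation = 3, n_per_class = 16,
                             n_samp = 120, seed = 1) {
  pair <- make_spd_pair(dim, separation, seed = seed)
  withr::with_seed(seed + 1, tibble::tibble(
    label = rep(c("walk", "intent"), each = n_per_class),
    repetition = rep(seq_len(n_per_class), 2),
    direction = "right",
    cov = c(sample_cov_epochs(pair$a, n_per_class, n_samp),
            sample_cov_epochs(pair$b, n_per_class, n_samp))))
}

# Per-trial epoch lists for the epoch-level cross-validation path.
epoch_trials <- function(n_trials = 8, dim = 6, separation = 3,
                         reps_per_trial = 7, n_samp = 80, seed = 1) {
  pair <- make_spd_pair(dim, separation, seed = seed)
  withr::with_seed(seed + 7, lapply(seq_len(n_trials), function(t) {
    tibble::tibble(
      label = rep(c("walk", "intent"), each = reps_per_trial),
      repetition = rep(seq_len(reps_per_trial), 2),
      direction = rep(c("left", "right"), length.out = 2 * reps_per_trial),
      cov = c(sample_cov_epochs(pair$a, reps_per_trial, n_samp),
              sample_cov_epochs(pair$b, reps_per_trial, n_samp)))
  }))
}

# A small synthetic session kept light for IO and pipeline tests.
small_session <- function(seed = 5, n_trials = 2, n_turns = 2) {
  gen_session(
    imu_params = imu_gen_params(n_turns = n_turns),
    eeg_params = eeg_gen_params(separation = 2, seed = seed),
    n_trials = n_trials, seed = seed)
}

# Wrap a generated IMU trial into a full trial object with silent EEG, for
# tests that only exercise the IMU path.
trial_from_imu <- function(g) {
  n_eeg <- length(g$imu$xz) * 10L
  zeros <- function(nc, labs) recording(
    matrix(0, n_eeg, nc, dimnames = list(NULL, labs)), fs = 500)
  trial(eeg = zeros(27, eeg_channel_names()),
        eog = zeros(4, eog_channel_names()),
        imu = g$imu, basal_end = g$basal_end,
        third_step_marks = g$third_step_marks,
        ground_truth = g$ground_truth)
}

# A synthetic prediction stream for the decision-logic tests.
prediction_stream <- function(labels, t_start = 1.2, shift = 0.2) {
  tibble::tibble(t_end_s = t_start + shift * (seq_along(labels) - 1),
                 label = labels)
}
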