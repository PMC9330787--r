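#' Sample covariance matrix of an epoch
#'
#' Mean-centers the window and returns `t(X) %*% X / (n - 1)`. If the result
#' is rank-deficient (minimum eigenvalue below `tol`), a small ridge
#' `eps * I` with `eps = 1e-10 * trace / n_channels` (floored at 1e-12) is
#' added so downstream Riemannian operations remain defined.
#'
#' @param window Numeric matrix, samples x channels.
#' @param tol Eigenvalue tolerance below which regularization kicks in.
#' @return An SPD matrix with attribute `"regularized"` (logical).
#' @export
scm <- function(window, tol = 1e-10) {
  window <- as.matrix(window)
  n <- nrow(window)
  if (n < 2) abort("Need at least two samples per window.")
  x <- sweep(window, 2, colMeans(window))
  s <- crossprod(x) / (n - 1)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  reg <- FALSE
  if (min(ev) < tol) {
    if (any(diag(s) == 0))
      warn("Zero-variance channel in window; covariance regularized.")
    eps <- max(1e-10 * sum(diag(s)) / ncol(s), 1e-12)
    s <- s + diag(eps, ncol(s))
    reg <- TRUE
  }
  attr(s, "regularized") <- reg
  s
}

#' Extract class windows around each valid turn
#'
#' For every valid repetition, cuts one monotonous-walk window (default
#' \[-6.0, -4.8) s) and one turn-intention window (default \[-1.4, -0.2) s)
#' relative to the IMU-detected change instant, each `epoch_len_s` long
#' (600 samples at 500 Hz). Windows that would start before the third-step
#' mark or before the recording are skipped.
#'
#' @param trial A [trial()] whose EEG has already been artifact-filtered and
#'   band-passed as desired.
#' @param turn_events Tibble from [detect_turn_events()] (or ground truth)
#'   with columns `change_time_s`, `direction` and, if QC was run, `valid`.
#' @param config A [run_config()].
#' @return A tibble with one row per window: `repetition`, `label`
#'   (`"walk"`/`"intent"`), `direction`, `t_start_s`, `t_end_s`, and a
#'   list-column `cov` of SPD matrices.
#' @export
extract_class_epochs <- function(trial, turn_events, config = run_config()) {
  fs <- trial$eeg$fs
  if (!nrow(turn_events)) return(empty_epochs())
  if ("valid" %in% names(turn_events))
    turn_events <- dplyr::filter(turn_events, .data$valid)
  marks <- trial$third_step_marks
  rows <- list()
  for (i in seq_len(nrow(turn_events))) {
    chg <- turn_events$change_time_s[i]
    dir <- turn_events$direction[i]
    mark <- if (length(marks)) max(marks[marks <= chg], -Inf) else -Inf
    for (lab in c("walk", "intent")) {
      w <- if (lab == "walk") config$walk_window else config$intent_window
      t_start <- chg + w[1]; t_end <- chg + w[2]
      i0 <- round((t_start - trial$eeg$t0) * fs)          # 0-based
      n <- round(config$epoch_len_s * fs)
      if (i0 < 0 || (is.finite(mark) && t_start < mark - 1e-9)) next
      if (i0 + n > nrow(trial$eeg$samples)) next
      win <- trial$eeg$samples[(i0 + 1):(i0 + n), , drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repetition = i, label = lab, direction = dir,
        t_start_s = t_start, t_end_s = t_end, cov = list(scm(win)))
    }
  }
  if (!length(rows)) return(empty_epochs())
  dplyr::bind_rows(rows)
}

empty_epochs <- function() {
  tibble::tibble(repetition = integer(), label = character(),
                 direction = character(), t_start_s = numeric(),
                 t_end_s = numeric(), cov = list())
}

#' Slide covariance epochs over a recording
#'
#' Causal sliding windows of `epoch_len_s` seconds stepped every `shift_s`
#' seconds; the time attached to each epoch is its end time, the instant at
#' which it becomes available to a real-time decoder.
#'
#' @param rec A [recording()].
#' @param config A [run_config()].
#' @return Tibble with `t_end_s` and list-column `cov`.
#' @export
sliding_epochs <- function(rec, config = run_config()) {
  fs <- rec$fs
  n_epoch <- round(config$epoch_len_s * fs)
  n_shift <- round(config$shift_s * fs)
  n <- nrow(rec$samples)
  starts <- seq(1L, n - n_epoch + 1L, by = n_shift)
  tibble::tibble(
    t_end_s = rec$t0 + (starts + n_epoch - 1L) / fs,
    cov = lapply(starts, function(s)
      scm(rec$samples[s:(s + n_epoch - 1L), , drop = FALSE])))
}
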