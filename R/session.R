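#' Multichannel recording
#'
#' A time-by-channel matrix of samples in microvolts with a sampling rate and
#' start time. The reader rejects non-finite samples: downstream filters and
#' covariance estimators assume finite data.
#'
#' @param samples Numeric matrix, time x channels.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (defaults to matrix column names).
#' @param t0 Start time in seconds.
#' @return A `recording` object.
#' @export
recording <- function(samples, fs, labels = colnames(samples), t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || fs <= 0)
    abort("fs must be positive.", class = "turnintent_data_error")
  if (any(!is.finite(samples)))
    abort("Recording contains NaN/Inf samples.",
          class = "turnintent_data_error")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(samples)))
  colnames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels, t0 = t0),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples x %d channels @ %g Hz, t0 = %g s (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$t0,
              nrow(x$samples) / x$fs))
  invisible(x)
}

rec_duration <- function(rec) nrow(rec$samples) / rec$fs
rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$samples)) - 1) / rec$fs

#' Back-IMU orientation trace
#'
#' Direction-cosine components `Xz` and `Yz` of the trunk sensor, sampled at
#' 50 Hz, from which the zenith-plane heading angle is derived.
#'
#' @param xz,yz Numeric vectors of equal length, dimensionless cosines.
#' @param fs Sampling rate in Hz (50 by convention).
#' @param t0 Start time in seconds.
#' @return An `imu_trace` object.
#' @export
imu_trace <- function(xz, yz, fs = 50, t0 = 0) {
  if (length(xz) != length(yz))
    abort("xz and yz must have equal length.", class = "turnintent_data_error")
  if (any(!is.finite(xz)) || any(!is.finite(yz)))
    abort("IMU trace contains NaN/Inf samples.",
          class = "turnintent_data_error")
  if (max(abs(c(xz, yz))) > 1 + 1e-6)
    abort("Direction cosines must lie in [-1, 1].",
          class = "turnintent_data_error")
  structure(list(xz = as.numeric(xz), yz = as.numeric(yz), fs = fs, t0 = t0),
            class = "imu_trace")
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$xz), x$fs, length(x$xz) / x$fs))
  invisible(x)
}

#' One walking trial
#'
#' Synchronized EEG (+EOG) and IMU streams for a trial that starts with a
#' standing basal period (default 15 s, used for adaptive-filter convergence)
#' followed by walking with spontaneous turns. `third_step_marks` give, per
#' repetition, the instant steady walking was established.
#'
#' @param eeg,eog [recording()]s at the EEG rate (500 Hz).
#' @param imu An [imu_trace()] covering the same wall-clock interval.
#' @param basal_end End of the basal period, seconds.
#' @param third_step_marks Times (s), one per repetition.
#' @param ground_truth Optional tibble of true events (synthetic sessions):
#'   columns `turn_time_s`, `direction`, `intent_onset_s`.
#' @return A `trial` object.
#' @export
trial <- function(eeg, eog, imu, basal_end, third_step_marks,
                  ground_truth = NULL) {
  stopifnot(inherits(eeg, "recording"), inherits(eog, "recording"),
            inherits(imu, "imu_trace"))
  if (basal_end < 0 || basal_end > rec_duration(eeg) + eeg$t0)
    abort("basal_end must lie within the recording.",
          class = "turnintent_data_error")
  imu_dur <- length(imu$xz) / imu$fs
  if (abs(imu_dur - rec_duration(eeg)) > 1 / imu$fs + 1e-9)
    abort("EEG and IMU must cover the same interval within one IMU period.",
          class = "turnintent_sync_error")
  if (nrow(eog$samples) != nrow(eeg$samples))
    abort("EEG and EOG must have identical length.",
          class = "turnintent_sync_error")
  structure(
    list(eeg = eeg, eog = eog, imu = imu, basal_end = basal_end,
         third_step_marks = as.numeric(third_step_marks),
         ground_truth = ground_truth),
    class = "trial")
}

#' A recording session
#'
#' @param trials List of [trial()]s.
#' @param asr_baseline [recording()] of >= 60 s of standing baseline used to
#'   calibrate artifact subspace reconstruction.
#' @param subject_id Identifier string.
#' @return A `session` object.
#' @export
session <- function(trials, asr_baseline, subject_id = "S1") {
  stopifnot(is.list(trials), inherits(asr_baseline, "recording"))
  if (rec_duration(asr_baseline) < 60 - 1e-9)
    abort("ASR baseline must be at least 60 s long.",
          class = "turnintent_data_error")
  structure(list(trials = trials, asr_baseline = asr_baseline,
                 subject_id = subject_id),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> subject %s: %d trials, %.0f s ASR baseline\n",
              x$subject_id, length(x$trials), rec_duration(x$asr_baseline)))
  invisible(x)
}
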