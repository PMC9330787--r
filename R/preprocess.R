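#' Preprocess a trial for covariance extraction
#'
#' Applies the configured artifact filter to the entire broadband recording
#' first (H-infinity against the EOG references, ASR against the session
#' baseline, or none), then isolates the configured frequency band with the
#' causal order-2 filter. This cascade order matters: artifact estimation
#' sees the broadband signal, band isolation comes last.
#'
#' @param trial A [trial()].
#' @param config A [run_config()].
#' @param asr_model An `asr_model` (required when
#'   `config$artifact_filter == "asr"`).
#' @param ... Passed to [hinf_filter()] / [asr_process()].
#' @return The trial with its `eeg` replaced by the filtered recording.
#' @export
preprocess_trial <- function(trial, config = run_config(), asr_model = NULL,
                             ...) {
  stopifnot(inherits(trial, "trial"))
  eeg <- switch(config$artifact_filter,
    hinf = hinf_filter(trial$eeg, trial$eog, ...),
    asr = {
      if (is.null(asr_model))
        abort("ASR filtering requires an asr_model.",
              class = "turnintent_config_error")
      asr_process(trial$eeg, asr_model, ...)
    },
    none = trial$eeg)
  trial$eeg <- bandpass(eeg, config$band)
  trial
}

#' Preprocess every trial of a session
#'
#' @param session A [session()].
#' @param config A [run_config()].
#' @return The session with all trials preprocessed; when ASR is configured
#'   the model is calibrated once on the session baseline.
#' @export
preprocess_session <- function(session, config = run_config()) {
  asr_model <- if (config$artifact_filter == "asr")
    asr_calibrate(session$asr_baseline) else NULL
  session$trials <- lapply(session$trials, preprocess_trial,
                           config = config, asr_model = asr_model)
  session
}
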