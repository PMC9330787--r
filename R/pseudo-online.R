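#' Adjudicate a causal prediction stream into detections
#'
#' Core decision logic shared by the pseudo-online simulator and the online
#' replay. Predictions are walked in time order within each repetition's
#' evaluated interval (third-step mark to IMU-detected change). A command
#' fires at every epoch whose last `mode` consecutive evaluated predictions
#' are all `"intent"` (any walk prediction resets the run); the decision
#' instant is the end time of that epoch. A decision inside
#' `[change - tp_margin_s, change]` is a true positive and halts the
#' repetition. Any other decision is a false positive; false positives are
#' only *counted* if at least `refractory_s` elapsed since the last counted
#' one (the refractory period suppresses counting, not prediction, and does
#' not reset the run).
#'
#' @param predictions Tibble with `t_end_s` and `label`
#'   (`"walk"`/`"intent"`), causally ordered.
#' @param repetitions Tibble with `repetition`, `start_s` (third-step mark)
#'   and `change_s` (IMU change instant).
#' @param config A [run_config()].
#' @return A `detection_timeline`: list with `timeline` (tibble of decision
#'   events: `repetition`, `t_s`, `adjudication`, `counted`), `repetitions`
#'   (with per-repetition `tp`, `n_fp`, `evaluated_s`), and `metrics`
#'   (one-row tibble: `tp_pct`, `fp_per_min`, `fp_ratio_pct`,
#'   `tp_no_fp_pct`, `n_repetitions`, `walking_time_min`).
#' @export
adjudicate_detections <- function(predictions, repetitions,
                                  config = run_config()) {
  predictions <- dplyr::arrange(predictions, .data$t_end_s)
  events <- list()
  rep_rows <- list()
  last_counted_fp <- -Inf
  for (i in seq_len(nrow(repetitions))) {
    r0 <- repetitions$start_s[i]; r1 <- repetitions$change_s[i]
    p <- dplyr::filter(predictions,
                       .data$t_end_s >= r0 - 1e-9,
                       .data$t_end_s <= r1 + 1e-9)
    run <- 0L; tp <- FALSE; n_fp <- 0L
    for (j in seq_len(nrow(p))) {
      run <- if (p$label[j] == "intent") run + 1L else 0L
      if (run >= config$mode) {
        td <- p$t_end_s[j]
        if (td >= r1 - config$tp_margin_s - 1e-9) {
          tp <- TRUE
          events[[length(events) + 1L]] <- tibble::tibble(
            repetition = repetitions$repetition[i], t_s = td,
            adjudication = "TP", counted = TRUE)
          break
        }
        counted <- td - last_counted_fp >= config$refractory_s - 1e-9
        if (counted) {
          last_counted_fp <- td
          n_fp <- n_fp + 1L
        }
        events[[length(events) + 1L]] <- tibble::tibble(
          repetition = repetitions$repetition[i], t_s = td,
          adjudication = "FP", counted = counted)
      }
    }
    rep_rows[[i]] <- tibble::tibble(
      repetition = repetitions$repetition[i],
      start_s = r0, change_s = r1,
      evaluated_s = r1 - r0, tp = tp, n_fp = n_fp)
  }
  reps <- dplyr::bind_rows(rep_rows)
  tl <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(repetition = integer(), t_s = numeric(),
                   adjudication = character(), counted = logical())
  walk_min <- sum(reps$evaluated_s) / 60
  metrics <- tibble::tibble(
    tp_pct = 100 * mean(reps$tp),
    fp_per_min = sum(reps$n_fp) / walk_min,
    fp_ratio_pct = 100 * mean(reps$n_fp > 0),
    tp_no_fp_pct = 100 * mean(reps$tp & reps$n_fp == 0),
    n_repetitions = nrow(reps),
    walking_time_min = walk_min)
  structure(list(timeline = tl, repetitions = reps, metrics = metrics),
            class = "detection_timeline")
}

#' @export
print.detection_timeline <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<detection_timeline> %d repetitions: TP %.1f%%, ",
                     "%.1f FP/min, FPRatio %.1f%%, TPnoFP %.1f%%\n"),
              m$n_repetitions, m$tp_pct, m$fp_per_min, m$fp_ratio_pct,
              m$tp_no_fp_pct))
  invisible(x)
}

#' @describeIn adjudicate_detections the decision events as a tibble.
#' @param x A `detection_timeline`.
#' @param ... Unused.
#' @export
tidy.detection_timeline <- function(x, ...) x$timeline

#' @describeIn adjudicate_detections the summary metrics as one row.
#' @export
glance.detection_timeline <- function(x, ...) x$metrics

#' Pseudo-online evaluation of a trained model
#'
#' Replays held-out trials through the causal real-time decision logic:
#' 1.2 s epochs slid every 0.2 s over the whole preprocessed trial, each
#' classified as walk or intent, with classification evaluated only between
#' the third-step mark and the IMU-detected change of each repetition, and
#' commands adjudicated by [adjudicate_detections()].
#'
#' @param session A [session()].
#' @param model A fitted `riemann_model` trained on trials disjoint from
#'   `test_trials`.
#' @param config A [run_config()] matching the model's filter/band.
#' @param test_trials Indices of the held-out trials (default the trials
#'   after the first 8).
#' @param asr_model Optional pre-calibrated `asr_model`.
#' @return A `detection_timeline` pooled over the test trials.
#' @export
pseudo_online <- function(session, model, config = run_config(),
                          test_trials = NULL, asr_model = NULL) {
  stopifnot(inherits(session, "session"))
  if (is.null(test_trials))
    test_trials <- setdiff(seq_along(session$trials), 1:8)
  if (!length(test_trials)) abort("No test trials.")
  if (config$artifact_filter == "asr" && is.null(asr_model))
    asr_model <- asr_calibrate(session$asr_baseline)

  all_preds <- list(); all_reps <- list(); rep_id <- 0L
  for (ti in test_trials) {
    tr <- session$trials[[ti]]
    events <- detect_turn_events(tr)
    ptr <- preprocess_trial(tr, config, asr_model = asr_model)
    ep <- sliding_epochs(ptr$eeg, config)
    p <- predict(model, ep$cov)
    preds <- tibble::tibble(t_end_s = ep$t_end_s, label = p$label)
    marks <- tr$third_step_marks
    reps <- tibble::tibble(
      repetition = rep_id + seq_len(nrow(events)),
      start_s = vapply(events$change_time_s, function(chg) {
        prev <- marks[marks <= chg]
        if (length(prev)) max(prev) else tr$basal_end
      }, numeric(1)),
      change_s = events$change_time_s)
    rep_id <- rep_id + nrow(events)
    res <- adjudicate_detections(preds, reps, config)
    all_preds[[length(all_preds) + 1L]] <- res
  }
  # pool trials: recompute metrics over the concatenated repetitions
  tl <- dplyr::bind_rows(lapply(all_preds, `[[`, "timeline"))
  reps <- dplyr::bind_rows(lapply(all_preds, `[[`, "repetitions"))
  walk_min <- sum(reps$evaluated_s) / 60
  metrics <- tibble::tibble(
    tp_pct = 100 * mean(reps$tp),
    fp_per_min = sum(reps$n_fp) / walk_min,
    fp_ratio_pct = 100 * mean(reps$n_fp > 0),
    tp_no_fp_pct = 100 * mean(reps$tp & reps$n_fp == 0),
    n_repetitions = nrow(reps),
    walking_time_min = walk_min)
  structure(list(timeline = tl, repetitions = reps, metrics = metrics),
            class = "detection_timeline")
}
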