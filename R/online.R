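#' Two-phase online replay
#'
#' Replays trials through the live validation protocol. After the basal
#' convergence period the subject walks without intending to turn: during
#' the first 4 s no command may fire (any command fails the trial
#' immediately), during the following 8 s commands are logged as false
#' positives and also fail the trial. Trials that pass enter phase 2, the
#' window from the end of phase 1 to the IMU-detected change: a command no
#' earlier than `tp_margin_s` before the change and no later than the change
#' is a true positive; a command outside that window is a phase-2 false
#' positive. For each true positive the anticipation of the first and last
#' classification of the consecutive run is recorded (they span
#' [command_span()] seconds).
#'
#' @param session A [session()].
#' @param model A fitted `riemann_model`.
#' @param config A [run_config()], typically [run_config_online()]
#'   (mode 4, 0.6 s margin).
#' @param trials Trial indices to replay (default all).
#' @param phase1_strict_s,phase1_logged_s Durations of the two phase-1
#'   segments (4 s and 8 s).
#' @param asr_model Optional pre-calibrated `asr_model`.
#' @return An `online_result`: list with `trials` (one row per trial:
#'   `trial`, `phase1_fp`, `fp_walk_time_s`, `phase2_fp`, `phase2_tp`,
#'   `first_command_pre_turn_s`, `last_command_pre_turn_s`) and `summary`
#'   (from [summarize_online_trials()]).
#' @export
online_replay <- function(session, model, config = run_config_online(),
                          trials = seq_along(session$trials),
                          phase1_strict_s = 4, phase1_logged_s = 8,
                          asr_model = NULL) {
  if (config$artifact_filter == "asr" && is.null(asr_model))
    asr_model <- asr_calibrate(session$asr_baseline)
  rows <- vector("list", length(trials))
  for (k in seq_along(trials)) {
    tr <- session$trials[[trials[k]]]
    events <- detect_turn_events(tr)
    if (!nrow(events))
      abort("No IMU-detected change in trial.",
            class = "turnintent_data_error")
    change <- events$change_time_s[1]
    ptr <- preprocess_trial(tr, config, asr_model = asr_model)
    ep <- sliding_epochs(ptr$eeg, config)
    p <- predict(model, ep$cov)
    walk0 <- tr$basal_end
    cue <- walk0 + phase1_strict_s + phase1_logged_s
    # commands: every epoch ending a run of `mode` consecutive intents,
    # evaluated from the start of walking up to the change
    lab <- p$label[ep$t_end_s >= walk0 & ep$t_end_s <= change]
    tt <- ep$t_end_s[ep$t_end_s >= walk0 & ep$t_end_s <= change]
    run <- 0L
    cmd <- numeric(0)
    for (j in seq_along(lab)) {
      run <- if (lab[j] == "intent") run + 1L else 0L
      if (run >= config$mode) cmd <- c(cmd, tt[j])
    }
    p1 <- cmd[cmd < cue]
    row <- tibble::tibble(
      trial = trials[k], phase1_fp = length(p1) > 0,
      fp_walk_time_s = if (length(p1)) p1[1] - walk0 else NA_real_,
      phase2_fp = NA, phase2_tp = NA,
      first_command_pre_turn_s = NA_real_,
      last_command_pre_turn_s = NA_real_)
    if (!row$phase1_fp) {
      p2 <- cmd[cmd >= cue]
      if (length(p2)) {
        td <- p2[1]
        ok <- td >= change - config$tp_margin_s - 1e-9 && td <= change + 1e-9
        row$phase2_tp <- ok
        row$phase2_fp <- !ok
        if (ok) {
          row$last_command_pre_turn_s <- change - td
          row$first_command_pre_turn_s <- change - td + command_span(config)
        }
      } else {
        row$phase2_tp <- FALSE
        row$phase2_fp <- FALSE
      }
    }
    rows[[k]] <- row
  }
  trials_tbl <- dplyr::bind_rows(rows)
  structure(list(trials = trials_tbl,
                 summary = summarize_online_trials(trials_tbl)),
            class = "online_result")
}

#' Summarize a two-phase online trial log
#'
#' Computes the headline metrics of the online protocol from a per-trial
#' adjudication table (as produced by [online_replay()] or loaded with
#' [read_online_log()]): the number of phase-1 failures, the percentage of
#' trials passing to phase 2, the phase-2 true-positive percentage among
#' evaluated trials, and the mean first/last command anticipations over the
#' true positives.
#'
#' @param trials Tibble with columns `phase1_fp`, `phase2_tp`, `phase2_fp`,
#'   `first_command_pre_turn_s`, `last_command_pre_turn_s`.
#' @return One-row tibble: `n_trials`, `n_phase1_fp`, `pass_rate_pct`,
#'   `phase2_tp_pct`, `n_phase2_fp`, `mean_first_command_s`,
#'   `mean_last_command_s`.
#' @export
summarize_online_trials <- function(trials) {
  n <- nrow(trials)
  fail1 <- sum(trials$phase1_fp)
  ev <- dplyr::filter(trials, !.data$phase1_fp)
  tps <- dplyr::filter(ev, .data$phase2_tp %in% TRUE)
  tibble::tibble(
    n_trials = n,
    n_phase1_fp = fail1,
    pass_rate_pct = 100 * (n - fail1) / n,
    phase2_tp_pct = if (nrow(ev)) 100 * mean(ev$phase2_tp %in% TRUE)
      else NA_real_,
    n_phase2_fp = sum(ev$phase2_fp %in% TRUE),
    mean_first_command_s = mean(tps$first_command_pre_turn_s),
    mean_last_command_s = mean(tps$last_command_pre_turn_s))
}

#' Read a two-phase online adjudication log
#'
#' Loads a CSV with one row per online trial in the layout written by
#' [online_replay()] (`trial`, `phase1_fp`, `fp_walk_time_s`, `phase2_fp`,
#' `phase2_tp`, `first_command_pre_turn_s`, `last_command_pre_turn_s`).
#' The package ships a reference 28-trial log from a published live
#' validation session at
#' `system.file("extdata", "online_validation_trials.csv",
#' package = "turnintent")`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_online_log <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  df$phase1_fp <- df$phase1_fp == 1
  for (col in c("phase2_fp", "phase2_tp")) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), NA, v == 1)
  }
  df
}

#' @export
print.online_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<online_result> %d trials: %d phase-1 FP ",
                     "(pass rate %.1f%%), phase-2 TP %.1f%%, ",
                     "anticipation %.2f -> %.2f s\n"),
              s$n_trials, s$n_phase1_fp, s$pass_rate_pct, s$phase2_tp_pct,
              s$mean_first_command_s, s$mean_last_command_s))
  invisible(x)
}

#' @describeIn online_replay per-trial adjudications as a tibble.
#' @param x An `online_result`.
#' @param ... Unused.
#' @export
tidy.online_result <- function(x, ...) x$trials

#' @describeIn online_replay one-row summary.
#' @export
glance.online_result <- function(x, ...) x$summary
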