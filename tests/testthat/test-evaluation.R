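test_that("accuracy and balance follow their definitions", {
  expect_equal(accuracy(rep("walk", 4), rep("walk", 4))$acc_total, 100)
  a <- accuracy(c("walk", "walk", "intent", "intent"),
                c("walk", "intent", "intent", "walk"))
  expect_equal(a$acc_total, 50)
  expect_equal(a$acc_walk, 50)
  expect_equal(a$acc_intent, 50)
  expect_error(accuracy(character(0), character(0)))

  expect_equal(balance(75, 75), 0)
  expect_equal(balance(50, 60), 20)
  expect_equal(balance(0, 50), Inf)
})

test_that("randomness level follows the adjusted-Wald bound", {
  expect_equal(randomness_level(60), 0.5 + 1.96 * sqrt(0.25 / 64))
  expect_equal(randomness_level(60), 0.6225, tolerance = 1e-4)
  n <- 1:200
  expect_true(all(diff(randomness_level(n)) < 0))
  expect_equal(randomness_level(1e9), 0.5, tolerance = 1e-4)
  expect_error(randomness_level(0))
})

test_that("class windows land where the protocol places them", {
  # a hand-built 100 s trial so window placement is fully controlled
  n_eeg <- 100 * 500
  withr::with_seed(15, samp <- matrix(rnorm(n_eeg * 27), ncol = 27,
                                      dimnames = list(NULL,
                                                      eeg_channel_names())))
  tr <- trial(
    eeg = recording(samp, 500),
    eog = recording(matrix(0, n_eeg, 4,
                           dimnames = list(NULL, eog_channel_names())), 500),
    imu = imu_trace(rep(0, n_eeg / 10), rep(1, n_eeg / 10)),
    basal_end = 10, third_step_marks = 12)
  ev <- tibble::tibble(change_time_s = 20, direction = "right")
  ep <- extract_class_epochs(tr, ev)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$t_start_s[ep$label == "walk"], 14.0)
  expect_equal(ep$t_end_s[ep$label == "walk"], 15.2)
  expect_equal(ep$t_start_s[ep$label == "intent"], 18.6)
  expect_equal(ep$t_end_s[ep$label == "intent"], 19.8)
  expect_equal(dim(ep$cov[[1]]), c(27, 27))
  # the walk window holds exactly 600 samples: [14.0, 15.2) at 500 Hz
  walk_cov <- ep$cov[[which(ep$label == "walk")]]
  expect_equal(walk_cov, scm(samp[7001:7600, ]))

  # 8 valid repetitions -> 16 windows
  ev8 <- tibble::tibble(change_time_s = seq(20, 90, by = 10),
                        direction = rep(c("right", "left"), 4))
  tr8 <- tr
  tr8$third_step_marks <- ev8$change_time_s - 8
  expect_equal(nrow(extract_class_epochs(tr8, ev8)), 16)

  # a window reaching before the recording start is skipped
  tr2 <- tr
  tr2$third_step_marks <- 1
  ev_early <- tibble::tibble(change_time_s = 5, direction = "left")
  expect_equal(nrow(extract_class_epochs(tr2, ev_early)), 1)  # walk skipped
})

test_that("leave-one-trial-out CV recovers separable classes and rejects
          shuffled labels", {
  ep <- epoch_trials(separation = 3, seed = 16)
  cfg <- run_config(classifier = "mdm")
  cv <- loto_cv(config = cfg, epochs = ep)
  expect_gt(cv$acc_total, 95)
  expect_true(cv$valid)
  expect_equal(cv$n_valid_repetitions, 8 * 7)
  expect_equal(nrow(cv$folds), 8)

  # same covariance for both classes: nothing to learn
  ep0 <- epoch_trials(separation = 0, seed = 17)
  cv0 <- loto_cv(config = cfg, epochs = ep0)
  expect_lt(cv0$acc_total, 100 * cv0$randomness_level + 15)

  g <- glance(cv)
  expect_true(g$valid)
  expect_s3_class(tidy(cv), "tbl_df")
})

test_that("directional model types use only their repetitions", {
  ep <- epoch_trials(separation = 3, reps_per_trial = 6, seed = 18)
  cfg <- run_config(classifier = "mdm")
  cv_l <- loto_cv(config = cfg, epochs = ep, model_type = "left_only")
  cv_b <- loto_cv(config = cfg, epochs = ep)
  expect_equal(cv_l$n_valid_repetitions, cv_b$n_valid_repetitions / 2)
  expect_gt(cv_l$randomness_level, cv_b$randomness_level)
})

test_that("configuration selection maximizes valid accuracy with tie rules", {
  grid <- tidyr::expand_grid(subject = c("A", "B"),
                             filter = "hinf",
                             band = c("8-14", "8-40"),
                             classifier = c("mdm", "ts_svm"))
  grid$acc <- c(70, 60, 55, 50,   # A
                70, 60, 55, 50)   # B
  grid$b <- 5; grid$valid <- TRUE

  gen <- select_configuration(grid, "generic")
  expect_equal(gen$selection$band, "8-14")
  expect_equal(gen$selection$classifier, "mdm")

  per <- select_configuration(grid, "personalized")
  expect_equal(nrow(per$selection), 2)
  expect_true(all(per$selection$acc >= gen$selection$acc - 1e-9))

  # equal accuracy: lower b wins
  grid2 <- grid[grid$subject == "A", ]
  grid2$acc <- 70
  grid2$b <- c(5, 2, 6, 7)
  sel2 <- select_configuration(grid2, "personalized")
  expect_equal(sel2$selection$b, 2)

  # invalid-only grids flag their selection
  grid3 <- grid2; grid3$valid <- FALSE
  expect_warning(sel3 <- select_configuration(grid3, "personalized"),
                 "no valid cell")
  expect_true(sel3$selection$flagged)
})

test_that("detection adjudication follows mode, margin and refractory rules", {
  cfg <- run_config(classifier = "mdm")
  reps <- tibble::tibble(repetition = 1L, start_s = 1.2, change_s = 16)

  # exactly mode consecutive intents ending inside the margin -> one TP
  labs <- rep("walk", 75)
  labs[71:75] <- "intent"   # t_end 15.2..16.0; decision at 16.0
  res <- adjudicate_detections(prediction_stream(labs), reps, cfg)
  expect_equal(res$metrics$tp_pct, 100)
  expect_equal(res$metrics$fp_per_min, 0)
  expect_equal(res$timeline$adjudication, "TP")
  expect_equal(res$timeline$t_s, 16)

  # a run broken by one walk prediction never fires
  labs2 <- labs; labs2[73] <- "walk"
  res2 <- adjudicate_detections(prediction_stream(labs2), reps, cfg)
  expect_equal(res2$metrics$tp_pct, 0)

  # early decision -> FP even though later ones fall in the margin
  labs3 <- rep("intent", 75)
  res3 <- adjudicate_detections(prediction_stream(labs3), reps, cfg)
  expect_equal(res3$metrics$tp_pct, 100)  # eventually reaches the margin
  expect_gt(sum(res3$timeline$adjudication == "FP"), 0)

  # counted FPs at least refractory_s apart
  counted <- res3$timeline$t_s[res3$timeline$adjudication == "FP" &
                                 res3$timeline$counted]
  expect_true(all(diff(counted) >= cfg$refractory_s - 1e-9))
})

test_that("an always-intent stream on 60 s yields exactly 30 FP/min", {
  cfg <- run_config(classifier = "mdm")
  # evaluated interval of exactly 60 s; epochs end every 0.2 s
  reps <- tibble::tibble(repetition = 1L, start_s = 10, change_s = 70)
  n <- 400
  preds <- prediction_stream(rep("intent", n), t_start = 9.0)
  preds <- dplyr::filter(preds, t_end_s <= 70 - cfg$tp_margin_s - 0.2)
  res <- adjudicate_detections(preds, reps, cfg)
  expect_equal(sum(res$repetitions$n_fp), 30)
  expect_equal(res$metrics$fp_per_min, 30)

  # always-walk: no decisions at all
  res0 <- adjudicate_detections(
    prediction_stream(rep("walk", n), t_start = 9.0), reps, cfg)
  expect_equal(res0$metrics$tp_pct, 0)
  expect_equal(res0$metrics$fp_per_min, 0)
})

test_that("FP/min equals brute-force counting on random streams", {
  cfg <- run_config(classifier = "mdm")
  withr::with_seed(20, {
    for (rep_i in 1:100) {
      n <- 120
      labs <- sample(c("walk", "intent"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
      start <- runif(1, 0, 2)
      change <- start + n * 0.2 + 1.2
      preds <- prediction_stream(labs, t_start = start + 1.2)
      reps <- tibble::tibble(repetition = 1L, start_s = start,
                             change_s = change)
      res <- adjudicate_detections(preds, reps, cfg)

      # independent brute force over the stream
      run <- 0; fp_times <- c(); tp <- FALSE; last <- -Inf
      for (j in seq_len(n)) {
        td <- preds$t_end_s[j]
        if (td < start || td > change) next
        run <- if (labs[j] == "intent") run + 1 else 0
        if (run >= 5) {
          if (td >= change - 0.4 - 1e-9) { tp <- TRUE; break }
          if (td - last >= 2 - 1e-9) { fp_times <- c(fp_times, td); last <- td }
        }
      }
      expect_equal(sum(res$repetitions$n_fp), length(fp_times))
      expect_equal(res$repetitions$tp, tp)
    }
  })
})

test_that("raising the mode never increases the counted FPs", {
  withr::with_seed(21, {
    labs <- sample(c("walk", "intent"), 200, replace = TRUE)
    preds <- prediction_stream(labs)
    reps <- tibble::tibble(repetition = 1L, start_s = 0, change_s = 100)
    fps <- vapply(2:8, function(m) {
      cfg <- run_config(mode = m, classifier = "mdm")
      sum(adjudicate_detections(preds, reps, cfg)$repetitions$n_fp)
    }, numeric(1))
    expect_true(all(diff(fps) <= 0))
  })
})

test_that("decision geometry identities hold", {
  expect_equal(tp_information_span(run_config()), 2.40)
  expect_equal(command_span(run_config_online()), 1.8)
  expect_equal(command_span(run_config()), 2.0)
})

test_that("online replay adjudicates phases and anticipation spans", {
  log <- read_online_log(system.file("extdata",
                                     "online_validation_trials.csv",
                                     package = "turnintent"))
  expect_equal(nrow(log), 28)
  # anticipation span equals the mode-4 command span on every TP row
  tp_rows <- dplyr::filter(log, phase2_tp %in% TRUE)
  expect_equal(tp_rows$first_command_pre_turn_s -
                 tp_rows$last_command_pre_turn_s,
               rep(command_span(run_config_online()), nrow(tp_rows)),
               tolerance = 1e-9)
  s <- summarize_online_trials(log)
  expect_equal(s$n_trials, 28)
  expect_equal(s$n_phase1_fp + round(s$pass_rate_pct / 100 * 28), 28)
})

test_that("online replay on synthetic streams produces coherent trials", {
  ses <- gen_session(imu_params = imu_gen_params(n_turns = 1),
                     eeg_params = eeg_gen_params(separation = 3, seed = 23),
                     n_trials = 3, seed = 23)
  cfg <- run_config_online(artifact_filter = "none", classifier = "mdm")
  ep <- lapply(ses$trials[1:2], function(tr) {
    # one turn per trial: the per-direction correlation criterion cannot
    # apply, which qc_repetitions reports with a warning
    ev <- suppressWarnings(qc_repetitions(tr, detect_turn_events(tr)))
    extract_class_epochs(preprocess_trial(tr, cfg), ev, cfg)
  })
  mod <- fit_riemann(dplyr::bind_rows(ep), "mdm", config = cfg)
  res <- online_replay(ses, mod, cfg, trials = 3)
  expect_equal(nrow(res$trials), 1)
  row <- res$trials[1, ]
  if (!row$phase1_fp && isTRUE(row$phase2_tp)) {
    expect_equal(row$first_command_pre_turn_s - row$last_command_pre_turn_s,
                 command_span(cfg))
    expect_gte(row$last_command_pre_turn_s, 0)
    expect_lte(row$last_command_pre_turn_s, cfg$tp_margin_s + 1e-9)
  }
  expect_s3_class(glance(res), "tbl_df")
})
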