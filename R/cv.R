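#' Leave-one-trial-out cross-validation
#'
#' Runs the offline validation protocol on the first `n_cv_trials` trials of
#' a session (default 8: one held out for testing, seven for the model, each
#' trial held out once). Per trial, turns are detected from the IMU, invalid
#' repetitions are discarded, class windows are cut and summarized as
#' covariance epochs, and the configured classifier is trained on the
#' training folds and evaluated on the held-out trial. Pooled test
#' predictions give the total and per-class accuracies, the balance
#' statistic, and the chance-level (randomness) filter: a result is valid
#' when `acc_total` exceeds the randomness level and `b <= 10`.
#'
#' @param session A [session()] (raw; preprocessing is applied per `config`
#'   unless `preprocess = FALSE`).
#' @param config A [run_config()].
#' @param model_type `"both"`, `"left_only"` or `"right_only"`: which turn
#'   directions contribute repetitions.
#' @param electrodes Optional channel-index subset; training and prediction
#'   use the principal submatrix of the covariances.
#' @param n_cv_trials Number of leading trials entering the CV.
#' @param preprocess Apply artifact filtering and band isolation first.
#' @param epochs Advanced: a list of per-trial epoch tibbles (as from
#'   [extract_class_epochs()]) to use directly, bypassing the session.
#' @param b_max Balance threshold for validity.
#' @return A `cv_result`.
#' @export
loto_cv <- function(session = NULL, config = run_config(),
                    model_type = c("both", "left_only", "right_only"),
                    electrodes = NULL, n_cv_trials = 8, preprocess = TRUE,
                    epochs = NULL, b_max = 10) {
  model_type <- match.arg(model_type)
  if (is.null(epochs)) {
    stopifnot(inherits(session, "session"))
    n_cv_trials <- min(n_cv_trials, length(session$trials))
    use <- session$trials[seq_len(n_cv_trials)]
    asr_model <- if (preprocess && config$artifact_filter == "asr")
      asr_calibrate(session$asr_baseline) else NULL
    epochs <- lapply(use, function(tr) {
      events <- qc_repetitions(tr, detect_turn_events(tr))
      if (preprocess)
        tr <- preprocess_trial(tr, config, asr_model = asr_model)
      extract_class_epochs(tr, events, config)
    })
  }
  if (model_type != "both") {
    keep_dir <- if (model_type == "left_only") "left" else "right"
    epochs <- lapply(epochs, function(e)
      dplyr::filter(e, .data$direction == keep_dir))
  }
  usable <- which(vapply(epochs, nrow, integer(1)) > 0)
  if (length(usable) < 2)
    abort("Need at least two trials with valid repetitions.",
          class = "turnintent_data_error")

  preds <- list()
  folds <- list()
  for (i in usable) {
    train <- dplyr::bind_rows(epochs[-i])
    test <- epochs[[i]]
    if (!nrow(test)) next
    model <- fit_riemann(train, classifier = config$classifier,
                         electrodes = electrodes, config = config)
    p <- predict(model, test$cov)
    preds[[length(preds) + 1L]] <-
      tibble::tibble(fold = i, truth = test$label, predicted = p$label)
    folds[[length(folds) + 1L]] <-
      dplyr::mutate(accuracy(test$label, p$label), fold = i)
  }
  preds <- dplyr::bind_rows(preds)
  acc <- accuracy(preds$truth, preds$predicted)
  n_valid <- sum(vapply(epochs[usable], function(e)
    length(unique(e$repetition[e$label == "intent"])), integer(1)))
  b <- balance(acc$acc_intent, acc$acc_total)
  rl <- randomness_level(max(n_valid, 1))
  structure(
    list(acc_total = acc$acc_total, acc_walk = acc$acc_walk,
         acc_intent = acc$acc_intent, b = b,
         randomness_level = rl, n_valid_repetitions = n_valid,
         valid = acc$acc_total > rl * 100 && b <= b_max,
         model_type = model_type, config = config,
         folds = dplyr::bind_rows(folds), predictions = preds),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("<cv_result> Acc %.1f%% (walk %.1f, intent %.1f), ",
                     "b %.1f, chance %.1f%%, %d valid repetitions -> %s\n"),
              x$acc_total, x$acc_walk, x$acc_intent, x$b,
              100 * x$randomness_level, x$n_valid_repetitions,
              if (x$valid) "valid" else "not valid"))
  invisible(x)
}

#' @describeIn loto_cv per-fold accuracies as a tibble.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @describeIn loto_cv one-row summary of the cross-validation.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(acc_total = x$acc_total, acc_walk = x$acc_walk,
                 acc_intent = x$acc_intent, b = x$b,
                 randomness_level = x$randomness_level,
                 n_valid_repetitions = x$n_valid_repetitions,
                 valid = x$valid, model_type = x$model_type)
}

#' Select a decoding configuration from a cross-validation grid
#'
#' Given a grid of CV results over artifact filters x bands x classifiers
#' (and subjects), picks either a generic configuration — the single
#' (filter, band, classifier) cell maximizing mean accuracy over the
#' subjects for which that cell is valid — or a personalized one, the
#' per-subject argmax over that subject's valid cells. Ties break toward
#' lower balance `b`, then the lower band index (band order of
#' [standard_bands()]). If a subject has no valid cell, the best invalid
#' cell is returned flagged, with a warning.
#'
#' @param grid Tibble with columns `subject`, `filter`, `band`,
#'   `classifier`, `acc`, `b`, `valid`.
#' @param strategy `"generic"` or `"personalized"`.
#' @return A `config_selection`: list with `strategy`, `selection` tibble
#'   and the input `grid`.
#' @export
select_configuration <- function(grid, strategy = c("generic",
                                                    "personalized")) {
  strategy <- match.arg(strategy)
  band_idx <- function(b) {
    i <- match(gsub("_", "-", b), standard_bands()$band)
    ifelse(is.na(i), length(standard_bands()$band) + 1L, i)
  }
  if (strategy == "generic") {
    cells <- grid %>%
      dplyr::filter(.data$valid) %>%
      dplyr::group_by(.data$filter, .data$band, .data$classifier) %>%
      dplyr::summarise(acc = mean(.data$acc), b = mean(.data$b),
                       n_subjects = dplyr::n(), .groups = "drop")
    if (!nrow(cells)) {
      warn("No valid cells in the grid; returning the best invalid cell.")
      cells <- grid %>%
        dplyr::group_by(.data$filter, .data$band, .data$classifier) %>%
        dplyr::summarise(acc = mean(.data$acc), b = mean(.data$b),
                         n_subjects = dplyr::n(), .groups = "drop")
      cells$flagged <- TRUE
    } else cells$flagged <- FALSE
    sel <- cells %>%
      dplyr::arrange(dplyr::desc(.data$acc), .data$b,
                     band_idx(.data$band)) %>%
      dplyr::slice(1)
  } else {
    pick_one <- function(g, subj) {
      v <- dplyr::filter(g, .data$valid)
      flagged <- !nrow(v)
      if (flagged) {
        warn(paste0("Subject ", subj,
                    " has no valid cell; best invalid cell returned."))
        v <- g
      }
      v %>%
        dplyr::arrange(dplyr::desc(.data$acc), .data$b,
                       band_idx(.data$band)) %>%
        dplyr::slice(1) %>%
        dplyr::mutate(flagged = flagged)
    }
    sel <- grid %>%
      dplyr::group_by(.data$subject) %>%
      dplyr::group_modify(~ pick_one(.x, .y$subject[[1]])) %>%
      dplyr::ungroup()
  }
  structure(list(strategy = strategy, selection = sel, grid = grid),
            class = "config_selection")
}

#' @export
print.config_selection <- function(x, ...) {
  cat("<config_selection>", x$strategy, "\n")
  print(x$selection)
  invisible(x)
}
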