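#' Classification accuracy with per-class breakdown
#'
#' Overall accuracy is `100 * correct / total`; per-class accuracies are
#' computed the same way within each true class.
#'
#' @param truth,predicted Character vectors of labels, equal nonempty length.
#' @return One-row tibble: `acc_total`, `acc_walk`, `acc_intent`, `n`.
#' @export
accuracy <- function(truth, predicted) {
  if (!length(truth) || length(truth) != length(predicted))
    abort("truth and predicted must be nonempty and of equal length.")
  per_class <- function(cls) {
    i <- truth == cls
    if (!any(i)) NA_real_ else 100 * mean(predicted[i] == truth[i])
  }
  tibble::tibble(acc_total = 100 * mean(predicted == truth),
                 acc_walk = per_class("walk"),
                 acc_intent = per_class("intent"),
                 n = length(truth))
}

#' Balance between change-class and total accuracy
#'
#' `b = 100 * |acc_intent - acc_total| / acc_intent`, the relative
#' discrepancy between the change-class accuracy and the total accuracy;
#' configurations with `b > 10` are considered one-sided and filtered out.
#' A zero change-class accuracy makes the statistic undefined and is
#' reported as `Inf` (worst case).
#'
#' @param acc_intent Change-class accuracy, percent.
#' @param acc_total Total accuracy, percent.
#' @return The balance statistic, percent.
#' @export
balance <- function(acc_intent, acc_total) {
  ifelse(acc_intent <= 0, Inf, 100 * abs(acc_intent - acc_total) / acc_intent)
}

#' Chance-level upper bound for two-class accuracy
#'
#' The adjusted-Wald upper confidence bound on a two-class chance accuracy
#' given the number of valid repetitions:
#' `0.5 + 1.96 * sqrt(0.5^2 / (n_valid + 4))`. A cross-validated accuracy is
#' only trusted if it exceeds this level. Monotone decreasing in `n_valid`,
#' approaching 0.5.
#'
#' @param n_valid Number of valid repetitions (>= 1).
#' @param z Normal quantile (1.96 for 95%).
#' @param p0 Chance proportion (0.5 for two balanced classes).
#' @return The randomness level as a fraction in (0.5, 1).
#' @export
randomness_level <- function(n_valid, z = 1.96, p0 = 0.5) {
  if (any(n_valid < 1)) abort("n_valid must be >= 1.")
  p0 + z * sqrt(p0^2 / (n_valid + 4))
}

#' Earliest instant whose samples can contribute to a valid detection
#'
#' A command needs `mode` consecutive intent epochs; the last may end no
#' earlier than `tp_margin_s` before the turn, so the first epoch of the run
#' opens `epoch_len_s + (mode - 1) * shift_s + tp_margin_s` before the turn.
#'
#' @param config A [run_config()].
#' @return Seconds before the change instant (positive).
#' @export
tp_information_span <- function(config = run_config()) {
  config$epoch_len_s + (config$mode - 1) * config$shift_s + config$tp_margin_s
}

#' First-to-last command span of a detection run
#'
#' When a command requires `mode` consecutive intent epochs, the first and
#' last epoch of the run end `(mode - 1) * shift_s` apart; the information
#' span from the start of the first epoch to the end of the last is
#' `epoch_len_s + (mode - 1) * shift_s`.
#'
#' @param config A [run_config()].
#' @return Seconds.
#' @export
command_span <- function(config = run_config()) {
  config$epoch_len_s + (config$mode - 1) * config$shift_s
}
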