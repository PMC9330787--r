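#' Calibrate artifact subspace reconstruction
#'
#' Learns clean-signal component statistics from a standing baseline of at
#' least 60 s. The baseline covariance is eigendecomposed into a calibration
#' basis; per-component RMS amplitudes are collected over sliding windows and
#' summarized as mean + `cutoff_k` standard deviations, giving one rejection
#' threshold per component.
#'
#' @param baseline A [recording()] of >= 60 s assumed artifact-light.
#' @param cutoff_k Threshold multiplier in baseline standard deviations
#'   (default 20, conservative).
#' @param window_s Sliding-window length in seconds (default 0.5).
#' @return An `asr_model`.
#' @export
asr_calibrate <- function(baseline, cutoff_k = 20, window_s = 0.5) {
  stopifnot(inherits(baseline, "recording"))
  if (rec_duration(baseline) < 60 - 1e-9)
    abort("ASR requires at least 60 s of baseline signal.",
          class = "turnintent_data_error")
  if (cutoff_k <= 0) abort("cutoff_k must be positive.")
  x <- sweep(baseline$samples, 2, colMeans(baseline$samples))
  c0 <- crossprod(x) / (nrow(x) - 1)
  e <- eigen((c0 + t(c0)) / 2, symmetric = TRUE)
  v <- e$vectors

  fs <- baseline$fs
  nw <- round(window_s * fs)
  starts <- seq(1L, nrow(x) - nw + 1L, by = nw %/% 2)
  rms <- t(vapply(starts, function(s) {
    y <- x[s:(s + nw - 1L), , drop = FALSE] %*% v
    sqrt(colMeans(y^2))
  }, numeric(ncol(x))))
  mu <- colMeans(rms); sig <- apply(rms, 2, sd)
  thresholds <- mu + cutoff_k * sig
  structure(
    list(basis = v, thresholds = thresholds, cutoff_k = cutoff_k,
         window_s = window_s, center = colMeans(baseline$samples),
         n_channels = ncol(x), fs = fs),
    class = "asr_model")
}

#' @export
print.asr_model <- function(x, ...) {
  cat(sprintf("<asr_model> %d channels, cutoff %g sd, window %.1f s\n",
              x$n_channels, x$cutoff_k, x$window_s))
  invisible(x)
}

#' Apply artifact subspace reconstruction
#'
#' Causal sliding-window processing stepped every `step_s` seconds: within
#' each window the data covariance is eigendecomposed, each window component
#' is compared against the calibration thresholds rotated into its direction
#' (variance above `sum(thresholds^2 * (basis' u)^2)` flags it), and flagged
#' components are removed by reconstructing the window from the retained
#' subspace. Each step emits only its new `step_s` chunk, so the output at
#' time t depends on samples up to the end of the current window only.
#' Samples before the first complete window pass through unchanged.
#'
#' @param eeg A [recording()] with the calibrated channel count.
#' @param model An `asr_model` from [asr_calibrate()].
#' @param step_s Step between window updates (default 0.2 s).
#' @return The cleaned [recording()].
#' @export
asr_process <- function(eeg, model, step_s = 0.2) {
  stopifnot(inherits(eeg, "recording"), inherits(model, "asr_model"))
  if (ncol(eeg$samples) != model$n_channels)
    abort("Channel count does not match the ASR calibration.",
          class = "turnintent_data_error")
  fs <- eeg$fs
  nw <- round(model$window_s * fs)
  ns <- round(step_s * fs)
  x <- eeg$samples
  n <- nrow(x)
  out <- x
  thr2 <- model$thresholds^2
  vb <- model$basis
  ends <- seq(nw, n, by = ns)
  for (e_i in ends) {
    win <- x[(e_i - nw + 1L):e_i, , drop = FALSE]
    wc <- sweep(win, 2, colMeans(win))
    cw <- crossprod(wc) / (nrow(wc) - 1)
    eg <- eigen((cw + t(cw)) / 2, symmetric = TRUE)
    # per-direction threshold: baseline thresholds rotated into u
    lim <- colSums(thr2 * crossprod(vb, eg$vectors)^2)
    keep <- eg$values <= lim
    if (all(keep)) {
      chunk <- win[(nw - ns + 1L):nw, , drop = FALSE]
    } else {
      proj <- eg$vectors[, keep, drop = FALSE]
      rec_win <- wc %*% proj %*% t(proj)
      rec_win <- sweep(rec_win, 2, colMeans(win), `+`)
      chunk <- rec_win[(nw - ns + 1L):nw, , drop = FALSE]
    }
    out[(e_i - ns + 1L):e_i, ] <- chunk
  }
  recording(out, fs = fs, labels = eeg$labels, t0 = eeg$t0)
}
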