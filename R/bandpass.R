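#' Causal order-2 band-pass filter with streaming state
#'
#' Butterworth band-pass of order 2 (a 4th-order transfer function) realized
#' in direct-form II transposed state variables, so the filter can be applied
#' chunk by chunk in real time: feeding the same signal in chunks with the
#' carried state reproduces the one-shot result exactly. No zero-phase
#' (forward-backward) filtering is used anywhere — the pipeline must remain
#' causal.
#'
#' @param rec A [recording()].
#' @param band A [band_spec()] or band label / `c(low, high)` Hz.
#' @param state Optional `filter_state` returned by a previous call, to
#'   continue filtering the next chunk of the same stream.
#' @param custom_band Allow non-standard bands.
#' @return The filtered [recording()] with the updated `filter_state`
#'   attached as attribute `"state"`.
#' @export
bandpass <- function(rec, band = "8-40", state = NULL, custom_band = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (!inherits(band, "band_spec")) band <- band_spec(band, custom_band)
  nyq <- rec$fs / 2
  if (band$high_hz >= nyq)
    abort("Band edge at or above Nyquist.", class = "turnintent_config_error")
  if (is.null(state)) {
    bt <- signal::butter(2, c(band$low_hz, band$high_hz) / nyq, type = "pass")
    z <- matrix(0, length(bt$b) - 1L, ncol(rec$samples))
    state <- structure(list(b = bt$b, a = bt$a, z = z, band = band$band),
                       class = "filter_state")
  } else {
    stopifnot(inherits(state, "filter_state"))
    if (state$band != band$band)
      abort("filter_state was created for a different band.",
            class = "turnintent_config_error")
  }
  res <- df2t_filter(state$b, state$a, rec$samples, state$z)
  state$z <- res$z
  out <- recording(res$y, fs = rec$fs, labels = rec$labels, t0 = rec$t0)
  attr(out, "state") <- state
  out
}

# Direct-form II transposed IIR across all channels at once; z is the
# (order x channels) state matrix carried between chunks.
df2t_filter <- function(b, a, x, z) {
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(x); m <- length(b) - 1L
  y <- matrix(0, n, ncol(x))
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    for (k in seq_len(m - 1L))
      z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
    z[m, ] <- b[m + 1L] * xt - a[m + 1L] * yt
    y[t, ] <- yt
  }
  list(y = y, z = z)
}
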