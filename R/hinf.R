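#' H-infinity adaptive ocular-artifact and drift removal
#'
#' Per EEG channel, an adaptive linear estimate of the artifact is regressed
#' out of the signal using the reference vector `[vEOG, hEOG, 1]`: the two
#' bipolar EOG derivations (vEOG = VU - VD, vertical; hEOG = HR - HL,
#' horizontal) capture blinks and saccades, and the constant bias term tracks
#' slow drift. The weights follow the gamma-suboptimal H-infinity recursion,
#' a worst-case-robust variant of recursive least squares: at each sample the
#' inverse-covariance-like matrix is inflated by `gamma^-2 r r'` before the
#' gain is computed, which keeps the filter permanently adaptive, and a small
#' process-noise term `q I` is added after each update. The recursion is
#' causal and single-pass; the leading basal seconds of each trial serve as
#' its convergence period.
#'
#' @param eeg A [recording()] of the 27 scalp channels (microvolts).
#' @param eog A [recording()] of the 4 EOG channels (HR, HL, VU, VD) at the
#'   same rate and length. An all-zero EOG is allowed, in which case only the
#'   bias (drift) term is active.
#' @param gamma Robustness bound, must exceed 1 (default 1.15).
#' @param q Process-noise scale (default 1e-10).
#' @return The cleaned [recording()], with the final weight matrix attached
#'   as attribute `"weights"` (3 x channels).
#' @export
hinf_filter <- function(eeg, eog, gamma = 1.15, q = 1e-10) {
  stopifnot(inherits(eeg, "recording"), inherits(eog, "recording"))
  if (gamma <= 1)
    abort("gamma must be > 1.", class = "turnintent_param_error")
  if (nrow(eog$samples) != nrow(eeg$samples) || eog$fs != eeg$fs)
    abort("EEG and EOG must share rate and length.",
          class = "turnintent_sync_error")
  x <- eeg$samples
  veog <- eog$samples[, "VU"] - eog$samples[, "VD"]
  heog <- eog$samples[, "HR"] - eog$samples[, "HL"]

  n <- nrow(x); nc <- ncol(x)
  w <- matrix(0, 3, nc)            # weights per channel over [vEOG, hEOG, 1]
  p <- diag(0.5, 3)
  g2 <- gamma^-2
  out <- matrix(0, n, nc)
  i3 <- diag(1, 3)
  for (t in seq_len(n)) {
    r <- c(veog[t], heog[t], 1)
    # inflate: Pt = (P^-1 - gamma^-2 r r')^-1, guarded to stay PD
    pinv <- chol2inv(chol(p)) - g2 * tcrossprod(r)
    pt <- tryCatch(chol2inv(chol((pinv + t(pinv)) / 2)),
                   error = function(e) p)
    denom <- 1 + as.numeric(crossprod(r, pt %*% r))
    g <- (pt %*% r) / denom
    e <- x[t, ] - as.numeric(crossprod(w, r))   # a-priori clean estimate
    out[t, ] <- e
    w <- w + g %*% rbind(e)
    p <- pt - tcrossprod(g, r) %*% pt + q * i3
    p <- (p + t(p)) / 2
  }
  res <- recording(out, fs = eeg$fs, labels = eeg$labels, t0 = eeg$t0)
  attr(res, "weights") <- w
  res
}
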