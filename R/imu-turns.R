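#' Zenith-plane heading angle from direction cosines
#'
#' Computes the trunk heading angle (degrees) from the back IMU's `Xz`, `Yz`
#' direction-cosine components via the quadrant-aware two-argument inverse
#' tangent, then unwraps it so turns accumulate continuously across quadrant
#' boundaries. `Xz = Yz = 0` leaves the angle undefined and is an error.
#'
#' @param trace An [imu_trace()].
#' @return Numeric vector of angles in degrees, same length as the trace.
#' @export
compute_zenith_angle <- function(trace) {
  stopifnot(inherits(trace, "imu_trace"))
  if (any(trace$xz == 0 & trace$yz == 0))
    abort("Undefined angle: Xz and Yz both zero at some sample.",
          class = "turnintent_data_error")
  ang <- atan2(trace$xz, trace$yz)
  # unwrap jumps larger than pi before converting to degrees
  d <- diff(ang)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ang[1], d)) * 180 / pi
}

#' Kernel smoothing of the heading angle
#'
#' Order-0 local regression (kernel-weighted local mean) with a Gaussian
#' kernel whose support spans `span` (a fraction of the series length), used
#' to suppress gait sway and sensor noise before curvature-based change
#' detection.
#'
#' @param angle Numeric vector (degrees).
#' @param span Window size as a fraction of the series length, in `(0, 1]`.
#' @param kernel Only `"gaussian"` is implemented.
#' @return Smoothed vector of the same length.
#' @export
smooth_angle <- function(angle, span = 0.02, kernel = "gaussian") {
  kernel <- match.arg(kernel, "gaussian")
  if (span <= 0 || span > 1) abort("span must lie in (0, 1].")
  n <- length(angle)
  half <- floor(n * span / 2)
  if (half < 1) {
    warn("Series shorter than the smoothing kernel support; passthrough.")
    return(angle)
  }
  # Gaussian weights truncated at the window edge (5 sd at the boundary);
  # a narrow kernel keeps the step's curvature peaks close to the step
  sigma <- half / 5
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  # kernel-weighted local mean with edge renormalization
  num <- as.numeric(stats::filter(angle, w, sides = 2))
  den <- as.numeric(stats::filter(rep(1, n), w, sides = 2))
  out <- num / den
  for (i in seq_len(half)) {      # edges: truncated kernel
    k <- w[(half + 2 - i):(2 * half + 1)]
    out[i] <- sum(angle[1:(i + half)] * k) / sum(k)
    k <- w[1:(half + i)]
    out[n - i + 1] <- sum(angle[(n - i + 1 - half):n] * k) / sum(k)
  }
  out
}

#' Locate the turn instant from the smoothed angle
#'
#' The second difference (discrete curvature) of the smoothed angle is
#' thresholded at `f` times its mean absolute value, with the factor `f`
#' stepping down from 6 to 1 until at least one sample exceeds it; the
#' earliest exceeding sample is the change point.
#'
#' @param smoothed Numeric vector from [smooth_angle()].
#' @return Integer change sample (index into the series).
#' @export
detect_turn <- function(smoothed) {
  n <- length(smoothed)
  if (n < 3) abort("Need at least three samples.")
  dd <- abs(diff(smoothed, differences = 2))
  m <- mean(dd)
  # a linear signal has (numerically) zero curvature everywhere
  if (max(dd) <= 1e-10 * max(1, max(abs(smoothed))))
    abort("No curvature in the signal: no turn detected.",
          class = "turnintent_noturn_error")
  for (f in 6:1) {
    hits <- which(dd > f * m)
    if (length(hits)) return(hits[1] + 1L)  # diff offset: dd[i] ~ sample i+1
  }
  abort("No curvature sample exceeded the mean: no turn detected.",
        class = "turnintent_noturn_error")
}

#' Label turn direction at a change sample
#'
#' The mean angle after the change is referenced to the mean before it;
#' a positive post-change mean is a right turn, otherwise left.
#'
#' @param angle Numeric vector (degrees) for one repetition window.
#' @param change_sample Change index from [detect_turn()].
#' @return A one-row tibble: `change_sample`, `direction`, `pre_mean_deg`,
#'   `post_mean_deg` (post mean referenced to the pre mean).
#' @export
label_direction <- function(angle, change_sample) {
  n <- length(angle)
  if (change_sample <= 1 || change_sample >= n)
    abort("change_sample must be strictly inside the window.")
  pre <- mean(angle[1:(change_sample - 1)])
  post <- mean(angle[(change_sample + 1):n]) - pre
  tibble::tibble(change_sample = as.integer(change_sample),
                 direction = if (post > 0) "right" else "left",
                 pre_mean_deg = pre, post_mean_deg = post)
}

#' Detect all turn events in a trial's IMU trace
#'
#' Segments the trace at the third-step marks (one repetition per mark, each
#' segment running to the next mark or the end of the trace), then runs
#' angle computation, smoothing, change detection and direction labeling per
#' repetition.
#'
#' @param trial A [trial()], or an [imu_trace()] plus explicit `marks`.
#' @param marks Third-step times (s); taken from the trial when omitted.
#' @param span Smoothing span, see [smooth_angle()].
#' @return Tibble with one row per repetition: `repetition`,
#'   `change_sample` (within the full trace), `change_time_s`, `direction`,
#'   `pre_mean_deg`, `post_mean_deg`.
#' @export
detect_turn_events <- function(trial, marks = NULL, span = 0.02) {
  imu <- if (inherits(trial, "trial")) trial$imu else trial
  if (is.null(marks)) {
    stopifnot(inherits(trial, "trial"))
    marks <- trial$third_step_marks
  }
  angle <- smooth_angle(compute_zenith_angle(imu), span = span)
  fs <- imu$fs
  n <- length(angle)
  bounds <- c(round((marks - imu$t0) * fs) + 1L, n)
  out <- vector("list", length(marks))
  for (i in seq_along(marks)) {
    seg <- bounds[i]:min(bounds[i + 1], n)
    ev <- label_direction(angle[seg], detect_turn(angle[seg]))
    ev$change_sample <- ev$change_sample + seg[1] - 1L
    ev$repetition <- i
    ev$change_time_s <- imu$t0 + (ev$change_sample - 1L) / fs
    out[[i]] <- ev
  }
  dplyr::bind_rows(out)[, c("repetition", "change_sample", "change_time_s",
                            "direction", "pre_mean_deg", "post_mean_deg")]
}

#' Quality-control of detected repetitions
#'
#' Flags repetitions that should not enter model creation:
#' \describe{
#'   \item{`mislabel_correlation`}{the repetition's aligned, pre-change-mean
#'     referenced angle profile correlates below 0.9 with the mean profile of
#'     its direction class;}
#'   \item{`mislabel_angle`}{its net angle increment deviates from the class
#'     mean increment by more than 25 degrees;}
#'   \item{`insufficient_walk_time`}{less than 6 s elapsed between the
#'     third-step mark and the change (too little monotonous walking for the
#'     walk-class window).}
#' }
#' A direction class with fewer than two members cannot define a mean
#' profile; its correlation criterion is suppressed with a warning.
#'
#' @param trial A [trial()].
#' @param events Tibble from [detect_turn_events()].
#' @param span Smoothing span used to rebuild the angle profiles.
#' @param cor_min,angle_tol_deg,min_walk_s Criterion thresholds.
#' @param align_s Half-width (s) of the profile aligned around each change.
#' @return `events` augmented with `walk_time_s`, `correlation`,
#'   `angle_increment_deg`, `reasons` (list-column) and `valid`.
#' @export
qc_repetitions <- function(trial, events, span = 0.02, cor_min = 0.9,
                           angle_tol_deg = 25, min_walk_s = 6,
                           align_s = 3) {
  imu <- trial$imu
  fs <- imu$fs
  angle <- smooth_angle(compute_zenith_angle(imu), span = span)
  half <- round(align_s * fs)
  n <- length(angle)

  profile_of <- function(cs) {
    idx <- (cs - half):(cs + half)
    ok <- idx >= 1 & idx <= n
    prof <- rep(NA_real_, length(idx))
    prof[ok] <- angle[idx[ok]]
    prof - mean(prof[seq_len(half)], na.rm = TRUE)  # reference pre-change mean
  }
  profs <- lapply(events$change_sample, profile_of)
  incr <- vapply(seq_len(nrow(events)), function(i) {
    p <- profs[[i]]
    mean(tail(p, half %/% 3), na.rm = TRUE) -
      mean(head(p, half %/% 3), na.rm = TRUE)
  }, numeric(1))

  marks <- trial$third_step_marks
  walk_time <- events$change_time_s -
    vapply(events$change_time_s, function(t) {
      prev <- marks[marks <= t]
      if (length(prev)) max(prev) else -Inf
    }, numeric(1))

  corr <- rep(NA_real_, nrow(events))
  for (d in unique(events$direction)) {
    i_d <- which(events$direction == d)
    if (length(i_d) < 2) {
      warn(paste0("Direction class '", d, "' has fewer than two members; ",
                  "correlation criterion suppressed."))
      next
    }
    pm <- do.call(cbind, profs[i_d])
    class_mean <- rowMeans(pm, na.rm = TRUE)
    for (i in i_d)
      corr[i] <- cor(profs[[i]], class_mean, use = "complete.obs")
  }
  mean_incr <- vapply(events$direction, function(d)
    mean(incr[events$direction == d]), numeric(1))

  reasons <- lapply(seq_len(nrow(events)), function(i) {
    r <- character(0)
    if (!is.na(corr[i]) && corr[i] < cor_min)
      r <- c(r, "mislabel_correlation")
    if (abs(incr[i] - mean_incr[i]) > angle_tol_deg)
      r <- c(r, "mislabel_angle")
    if (walk_time[i] < min_walk_s)
      r <- c(r, "insufficient_walk_time")
    r
  })

  dplyr::mutate(events,
                walk_time_s = walk_time,
                correlation = corr,
                angle_increment_deg = incr,
                reasons = reasons,
                valid = lengths(reasons) == 0L)
}
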