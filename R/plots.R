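#' Plot the IMU heading angle with detected turns
#'
#' @param trial A [trial()].
#' @param events Tibble from [detect_turn_events()] (detected if omitted).
#' @param span Smoothing span.
#' @return A ggplot.
#' @export
plot_turn_detection <- function(trial, events = NULL, span = 0.02) {
  if (is.null(events)) events <- detect_turn_events(trial, span = span)
  imu <- trial$imu
  ang <- compute_zenith_angle(imu)
  df <- tibble::tibble(
    t = imu$t0 + (seq_along(ang) - 1) / imu$fs,
    raw = ang,
    smoothed = smooth_angle(ang, span = span))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$change_time_s,
                                     colour = .data$direction),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "zenith-plane angle (deg)",
                  colour = "turn") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.detection_timeline <- function(object, ...) {
  reps <- object$repetitions
  tl <- object$timeline
  tl$pre_turn_s <- tl$t_s -
    reps$change_s[match(tl$repetition, reps$repetition)]
  ggplot2::ggplot(tl, ggplot2::aes(x = .data$pre_turn_s,
                                   y = factor(.data$repetition),
                                   colour = .data$adjudication,
                                   alpha = .data$counted)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_colour_manual(values = c(TP = "forestgreen",
                                            FP = "firebrick")) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "time relative to turn (s)", y = "repetition",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.electrode_ranking <- function(object, ...) {
  v <- object$v
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df <- dplyr::filter(df, .data$col >= .data$row)
  df$value <- v[cbind(df$row, df$col)]
  df$row_lab <- factor(object$labels[df$row], levels = object$labels)
  df$col_lab <- factor(object$labels[df$col], levels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_lab, y = .data$row_lab,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "|mean cov\ndifference|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heat map of a cross-validation grid
#'
#' @param grid Tibble with `band`, `classifier`, `acc`, and optionally
#'   `filter`.
#' @return A ggplot.
#' @export
plot_cv_grid <- function(grid) {
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$band,
                                          y = .data$classifier,
                                          fill = .data$acc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$acc)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "band (Hz)", y = NULL, fill = "Acc (%)") +
    ggplot2::theme_minimal()
  if ("filter" %in% names(grid))
    p <- p + ggplot2::facet_wrap(~filter)
  p
}
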