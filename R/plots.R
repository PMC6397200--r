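# ggplot2 helpers for the main result types.

#' Plot an ensemble MSD curve
#'
#' @param emsd Output of [ensemble_msd()].
#' @param log_log Draw on log-log axes (useful for reading the anomalous
#'   exponent)? Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_msd <- function(emsd, log_log = FALSE) {
  p <- ggplot2::ggplot(emsd, ggplot2::aes(x = .data$lag_s,
                                          y = .data$msd_mean_um2)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$msd_mean_um2 - .data$msd_sem_um2,
                   ymax = .data$msd_mean_um2 + .data$msd_sem_um2),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
  if (log_log) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot a velocity distribution with its polynomial fit
#'
#' @param object A `velocity_distribution` from [velocity_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_distribution <- function(object, ...) {
  h <- object$histogram
  grid <- tibble::tibble(
    bin_center_um_s = seq(min(h$bin_center_um_s), max(h$bin_center_um_s),
                          length.out = 200)
  )
  grid$fit <- as.numeric(
    stats::setNames(
      outer(grid$bin_center_um_s, seq_along(object$coefficients) - 1L, `^`) %*%
        object$coefficients,
      NULL
    )
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_center_um_s,
                                  y = .data$fraction)) +
    ggplot2::geom_col(width = object$bin_width_um_s * 0.9, alpha = 0.6) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), linetype = "dashed") +
    ggplot2::labs(x = expression(V[avg] ~ (mu * m / s)),
                  y = "fraction of tracks") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity trace with its detected bursts
#'
#' @param traces Trace table (columns `fiber_id`, `frame`, `intensity`).
#' @param fiber Fiber id to plot (default: the first).
#' @param events Optional burst table from [detect_bursts()].
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, fiber = NULL, events = NULL) {
  if (is.null(fiber)) fiber <- traces$fiber_id[1]
  tr <- traces[traces$fiber_id == fiber, , drop = FALSE]
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$frame,
                                        y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = fiber, x = "frame", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- events[events$fiber_id == fiber, , drop = FALSE]
    if (nrow(ev) > 0L) {
      shade <- tibble::tibble(
        xmin = tr$frame[ev$start_frame],
        xmax = tr$frame[ev$start_frame + ev$n_frames - 1L]
      )
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.2, fill = "red"
      )
    }
  }
  p
}

#' Plot a motor-neuron survival timecourse
#'
#' @param timecourse Output of [group_timecourse()].
#' @return A ggplot object with mean +/- SEM per condition over days.
#' @export
plot_timecourse <- function(timecourse) {
  ggplot2::ggplot(timecourse,
                  ggplot2::aes(x = .data$day, y = .data$mean_percent,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_percent - .data$sem_percent,
                   ymax = .data$mean_percent + .data$sem_percent)
    ) +
    ggplot2::labs(x = "day of co-culture", y = "surviving MNs (%)") +
    ggplot2::theme_minimal()
}
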