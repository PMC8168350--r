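#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic EMG stream
#'
#' One facet per channel, signal in microvolts against time.
#'
#' @param object An `emg_stream` from [emg_generate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_stream <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"time_ms",
                              names_to = "channel", values_to = "uV")
  long$channel <- factor(long$channel,
                         levels = setdiff(names(object), "time_ms"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$uV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "potential (µV)") +
    ggplot2::theme_minimal()
}

#' Plot the detections and alerts of a pipeline run
#'
#' Per-channel raw ADWIN detections as points, with the Planner's fired
#' alert windows shaded — the at-a-glance view of how many raw detections
#' the voting rule collapsed into alerts.
#'
#' @param object A `drift_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drift_run <- function(object, ...) {
  ch <- object$channel_summary$identifier
  pts <- object$drift_positions
  pts$identifier <- factor(pts$identifier, levels = rev(ch))
  p <- ggplot2::ggplot()
  if (nrow(object$alerts)) {
    p <- p + ggplot2::geom_rect(
      data = object$alerts,
      ggplot2::aes(xmin = .data$window_start_ms,
                   xmax = .data$window_end_ms,
                   ymin = -Inf, ymax = Inf),
      fill = "black", alpha = 0.15)
  }
  p +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$timestamp_ms, y = .data$identifier),
      colour = "red", size = 0.8) +
    ggplot2::scale_y_discrete(limits = rev(ch), drop = FALSE) +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = "Raw drift detections (points) and fired alerts (shaded)") +
    ggplot2::theme_minimal()
}
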