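#' Plot an averaged t-value histogram
#'
#' Grouped bars of mean per-bin voxel counts with Cousineau-Morey
#' within-subject error bars, plus vertical lines at the counting
#' criterion.
#'
#' @param object A `histogram_summary` from [average_histograms()].
#' @param t_crit Criterion lines to draw (`NULL` for none).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot histogram_summary
#' @export
autoplot.histogram_summary <- function(object, t_crit = 2.819, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin_mid, y = .data$mean, fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.75) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3) +
    ggplot2::labs(x = "t value (bin centre)", y = "voxels per bin",
                  fill = NULL)
  if (!is.null(t_crit)) {
    p <- p + ggplot2::geom_vline(xintercept = c(-t_crit, t_crit),
                                 linetype = "dashed")
  }
  p
}

#' Plot a block-locked ROI time course
#'
#' Mean percent signal change with a +/- SD ribbon; the task block is
#' shaded and the cue marked at onset.
#'
#' @param object An `event_locked_course` from
#'   [extract_roi_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot event_locked_course
#' @export
autoplot.event_locked_course <- function(object, ...) {
  block_s <- attr(object, "block_s")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::annotate("rect", xmin = 0, xmax = block_s, ymin = -Inf,
                      ymax = Inf, alpha = 0.12) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from block onset (s)",
                  y = "signal change (%)",
                  title = attr(object, "condition"))
  cue <- attr(object, "cue_s")
  if (!is.na(cue)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = cue,
                               ymin = -Inf, ymax = Inf, alpha = 0.3)
  }
  p
}

#' Plot a respiration trace
#'
#' @param object A `breath_trace` from [generate_respiration()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breath_trace
#' @export
autoplot.breath_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$flow)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "airflow (positive = inhale)")
}

#' Plot per-subject antagonism indices by task
#'
#' @param object A `distribution_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distribution_summary
#' @export
autoplot.distribution_summary <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$task, y = .data$antagonism)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_boxplot(outliers = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "antagonism index (P - N) / (P + N)")
}
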