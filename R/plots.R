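#' Block-averaged learning curves
#'
#' Optimal-choice rate per 10-trial block, averaged across sessions within
#' each task x treatment arm, with an s.e.m. ribbon.
#'
#' @param trials Trial tibble (one or many sessions).
#' @param block Block length in trials.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(trials, block = 10L) {
  meta <- dplyr::distinct(trials, .data$session_id, .data$task, .data$treatment)
  curve <- block_optimal_rate(trials, block = block) |>
    dplyr::left_join(meta, by = "session_id") |>
    dplyr::group_by(.data$task, .data$treatment, .data$block) |>
    dplyr::summarise(rate = mean(.data$rate),
                     sem = sd(.data$rate) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$block, y = .data$rate,
                                      colour = .data$treatment,
                                      fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - .data$sem,
                                      ymax = .data$rate + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$task), scales = "free_x") +
    ggplot2::labs(x = sprintf("%d-trial block", block),
                  y = "optimal choice rate") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Phase-wise optimal-choice rates per arm
#'
#' @param trials Trial tibble with at least one reversal per session.
#' @return A ggplot object (points: session means; crossbar: arm mean).
#' @export
plot_phase_rates <- function(trials) {
  rates <- phase_rates(trials)
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$phase, y = .data$rate,
                                      colour = .data$treatment)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          position = ggplot2::position_dodge(width = 0.5),
                          linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(y = "optimal choice rate") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot method for pipeline reports
#'
#' @param object An `rl_report` from [run_pipeline()].
#' @param type `"curve"` (block learning curves) or `"phase"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rl_report <- function(object, type = c("curve", "phase"), ...) {
  type <- match.arg(type)
  if (type == "curve") plot_learning_curve(object$sessions)
  else plot_phase_rates(object$sessions)
}
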