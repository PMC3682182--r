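#' Plot a fitted learning curve
#'
#' Raw per-block inverse efficiency (points) with the fitted exponential
#' (line).
#'
#' @param object A [fit_learning_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = block)) +
    ggplot2::geom_point(ggplot2::aes(y = ie_raw), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = ie_fitted), colour = "#b2182b",
                       linewidth = 0.8) +
    ggplot2::labs(x = "Block", y = "Inverse efficiency (s)",
                  title = sprintf("y = %.2f exp(-%.3f x)", object$a,
                                  object$b)) +
    ggplot2::theme_minimal()
}

#' Plot relative log evidences of the model space
#'
#' Bar chart of the summed log evidence per model, relative to the weakest
#' model, with the winner highlighted.
#'
#' @param object A [fixed_effects_bms()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bms_result <- function(object, ...) {
  d <- tidy(object)
  d$model <- factor(d$model, levels = names(object$summed))
  d$winner <- d$model %in% object$winner
  ggplot2::ggplot(d, ggplot2::aes(x = model, y = relative_log_evidence,
                                  fill = winner)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "Relative log evidence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the group coupling time-course
#'
#' Mean run-wise coupling change (relative to the first rest run) with SEM
#' error bars, per connection — the group-level picture of when and where
#' coupling changed.
#'
#' @param coupling Tibble with `connection`, `run`, `mean_change`, `sem`
#'   (as produced by [run_pipeline()]), or per-subject `change` values
#'   from [coupling_timecourse()] (then aggregated here).
#' @return A ggplot object.
#' @export
plot_coupling_timecourse <- function(coupling) {
  if ("change" %in% names(coupling) && !"mean_change" %in% names(coupling)) {
    coupling <- coupling %>%
      group_by(connection, run) %>%
      summarise(mean_change = mean(change),
                sem = stats::sd(change) / sqrt(dplyr::n()),
                .groups = "drop")
  }
  ggplot2::ggplot(coupling,
                  ggplot2::aes(x = factor(run), y = mean_change)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_change - sem,
                                        ymax = mean_change + sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~connection) +
    ggplot2::labs(x = "Rest run", y = "Coupling change (Hz)") +
    ggplot2::theme_minimal()
}
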