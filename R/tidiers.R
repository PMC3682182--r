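#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted learning curve
#'
#' @param x A [fit_learning_curve()] result.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`a`, `b`).
#' @export
tidy.learning_curve <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.learning_curve
#' @return `glance()`: one-row tibble with fit summaries.
#' @export
glance.learning_curve <- function(x, ...) {
  tibble(a = x$a, b = x$b, rss = x$rss, n_blocks = x$n_blocks,
         excluded_trials = x$excluded_trials,
         negative_rate = x$flagged_negative_rate)
}

#' Tidy a fitted DCM
#'
#' @param x A [fit_dcm()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (MAP) and `posterior_sd`.
#' @export
tidy.dcm_fit <- function(x, ...) {
  tibble(term = names(x$theta), estimate = unname(x$theta),
         posterior_sd = unname(x$posterior_sd))
}

#' @rdname tidy.dcm_fit
#' @return `glance()`: one-row tibble with the log evidence and
#'   convergence diagnostics.
#' @export
glance.dcm_fit <- function(x, ...) {
  tibble(model = x$spec$name, log_evidence = x$log_evidence,
         log_joint = x$log_joint, n_params = length(x$theta),
         n_volumes = x$n_volumes,
         converged = x$convergence$code == 0,
         hessian_pd = x$convergence$hessian_pd)
}

#' Tidy a Bayesian model selection result
#'
#' @param x A [fixed_effects_bms()] result.
#' @param ... Unused.
#' @return Tibble with one row per model: summed and relative log
#'   evidence, number of subjects for whom the model wins.
#' @export
tidy.bms_result <- function(x, ...) {
  tibble(
    model = names(x$summed),
    summed_log_evidence = unname(x$summed),
    relative_log_evidence = unname(x$relative),
    n_subject_wins = vapply(names(x$summed),
                            function(m) sum(x$per_subject_winner == m), 1L)
  )
}

#' @rdname tidy.bms_result
#' @return `glance()`: one-row summary with the winner and criterion.
#' @export
glance.bms_result <- function(x, ...) {
  tibble(winner = paste(x$winner, collapse = "/"), delta = x$delta,
         criterion = x$criterion, criterion_met = x$criterion_met,
         n_subjects = nrow(x$log_ev), n_models = ncol(x$log_ev))
}
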