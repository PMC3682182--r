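#' Exclude reaction-time outliers per block
#'
#' Removes, in a single pass, responded trials whose reaction time deviates
#' from the mean of their (condition, block) cell by more than
#' `n_sd` sample standard deviations (n - 1 denominator). Omitted trials
#' (`rt_s` is `NA`) are never excluded here: they carry no RT.
#'
#' @param trials Trial table with columns `condition`, `block`, `rt_s`
#'   (see [gen_behavior()]).
#' @param n_sd Exclusion threshold in SD units.
#' @return The filtered tibble, with the number of removed trials in
#'   attribute `"n_excluded"` (also retrievable with [n_excluded()]).
#' @export
#' @examples
#' tt <- tibble::tibble(condition = "motion", block = 1,
#'                      rt_s = c(rep(0.5, 10), 3), correct = 1)
#' nrow(exclude_rt_outliers(tt))
exclude_rt_outliers <- function(trials, n_sd = 3) {
  for (nm in c("condition", "block", "rt_s")) {
    if (!nm %in% names(trials)) {
      abort_restdcm(sprintf("column `%s` missing from trial table", nm),
                    "restdcm_parameter_error")
    }
  }
  counts <- trials %>%
    group_by(condition, block) %>%
    summarise(n_resp = sum(!is.na(rt_s)), .groups = "drop")
  if (nrow(counts) == 0 || any(counts$n_resp < 2)) {
    abort_restdcm("every block needs at least two responded trials",
                  "restdcm_parameter_error")
  }
  out <- trials %>%
    group_by(condition, block) %>%
    mutate(.deviant = !is.na(rt_s) &
             abs(rt_s - mean(rt_s, na.rm = TRUE)) >
               n_sd * sd(rt_s, na.rm = TRUE)) %>%
    ungroup()
  n_exc <- sum(out$.deviant)
  out <- out %>% filter(!.deviant) %>% select(-".deviant")
  attr(out, "n_excluded") <- n_exc
  out
}

#' @rdname exclude_rt_outliers
#' @param x A table returned by [exclude_rt_outliers()].
#' @export
n_excluded <- function(x) {
  v <- attr(x, "n_excluded")
  if (is.null(v)) 0L else v
}

#' Per-block inverse efficiency
#'
#' Inverse efficiency (IE) combines speed and accuracy:
#' `IE = mean reaction time / accuracy` (s; lower is better). The mean RT
#' is taken over responded trials; accuracy is the fraction of correct
#' trials in the block, with omitted responses counting as errors. Blocks
#' are returned in presentation order.
#'
#' @param trials Trial table (outliers already excluded, see
#'   [exclude_rt_outliers()]).
#' @param condition Condition to score (default `"motion"`; set `NULL` to
#'   score each condition separately for diagnostics).
#' @return Tibble with `condition`, `block`, `n_trials`, `accuracy`,
#'   `mean_rt`, `ie`.
#' @export
#' @examples
#' tt <- tibble::tibble(condition = "motion", block = 1,
#'                      rt_s = c(0.5, 0.7), correct = c(1, 0))
#' block_inverse_efficiency(tt)$ie # 0.6 / 0.5 = 1.2
block_inverse_efficiency <- function(trials, condition = "motion") {
  if (!is.null(condition)) {
    trials <- trials[trials$condition %in% condition, ]
    if (nrow(trials) == 0) {
      abort_restdcm("no trials for the requested condition",
                    "restdcm_parameter_error")
    }
  }
  out <- trials %>%
    group_by(condition, block) %>%
    summarise(
      n_trials = dplyr::n(),
      accuracy = mean(correct),
      mean_rt = mean(rt_s, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    arrange(condition, block)
  if (any(out$accuracy == 0)) {
    bad <- out$block[out$accuracy == 0]
    abort_restdcm(
      sprintf("inverse efficiency undefined: zero accuracy in block(s) %s",
              paste(bad, collapse = ", ")),
      "restdcm_degenerate_error"
    )
  }
  out$ie <- out$mean_rt / out$accuracy
  out
}

#' Fit the exponential learning curve
#'
#' Fits `y = a * exp(-b * x)` to the per-block inverse-efficiency values by
#' nonlinear least squares (Levenberg--Marquardt), where `x` is the block
#' index (starting at 1 by convention; configurable via `x`), `a` the
#' amplitude and `b` the learning rate. Multiple starting values for `b`
#' are tried and the fit with the lowest residual sum of squares is kept.
#' The fitted values are the quantity that enters the first-level GLM as a
#' parametric modulator. A negative `b` (performance worsening) is
#' permitted but flagged.
#'
#' @param ie Numeric vector of per-block IE values (or the tibble returned
#'   by [block_inverse_efficiency()], whose `ie` column is used).
#' @param x Block indices (default `1:n`).
#' @param b_starts Starting values for the learning rate.
#' @param excluded_trials Number of RT outliers removed upstream (recorded
#'   in the result).
#' @return Object of class `learning_curve` with elements `a`, `b`,
#'   `ie_raw`, `ie_fitted`, `rss`, `n_blocks`, `excluded_trials`,
#'   `flagged_negative_rate` and `curve` (tibble: block, ie_raw,
#'   ie_fitted). Supports [tidy()], [glance()] and `autoplot()`.
#' @export
#' @examples
#' ie <- 2 * exp(-0.1 * (1:25))
#' fit <- fit_learning_curve(ie)
#' c(fit$a, fit$b)
fit_learning_curve <- function(ie, x = NULL,
                               b_starts = c(0.01, 0.05, 0.2),
                               excluded_trials = 0L) {
  if (is.data.frame(ie)) {
    excluded_trials <- max(excluded_trials, n_excluded(ie))
    ie <- ie$ie
  }
  ie <- as.numeric(ie)
  if (length(ie) < 3L) {
    abort_restdcm("need at least three blocks to fit the learning curve",
                  "restdcm_parameter_error")
  }
  if (any(!is.finite(ie)) || any(ie <= 0)) {
    abort_restdcm("IE values must be positive and finite",
                  "restdcm_parameter_error")
  }
  if (is.null(x)) x <- seq_along(ie)
  dat <- data.frame(x = x, y = ie)
  best <- NULL
  statuses <- character(0)
  for (b0 in b_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-b * x), data = dat,
        start = list(a = ie[1], b = b0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      statuses <- c(statuses, conditionMessage(fit))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort_restdcm(
      paste0("learning-curve fit did not converge from any start: ",
             paste(unique(statuses), collapse = "; ")),
      "restdcm_convergence_error"
    )
  }
  cf <- coef(best$fit)
  fitted_vals <- as.numeric(cf[["a"]] * exp(-cf[["b"]] * x))
  structure(
    list(
      a = unname(cf[["a"]]), b = unname(cf[["b"]]),
      ie_raw = ie, ie_fitted = fitted_vals, x = x,
      rss = best$rss, n_blocks = length(ie),
      excluded_trials = excluded_trials,
      flagged_negative_rate = cf[["b"]] < 0,
      curve = tibble(block = x, ie_raw = ie, ie_fitted = fitted_vals)
    ),
    class = "learning_curve"
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve> y = a * exp(-b * x)\n")
  cat(sprintf("  a = %.4f s, b = %.4f per block (%d blocks, RSS %.4g)\n",
              x$a, x$b, x$n_blocks, x$rss))
  if (x$flagged_negative_rate) cat("  note: negative learning rate\n")
  invisible(x)
}

#' Flag ceiling and floor performers
#'
#' Mirrors the behavioral screening of a learning cohort: subjects at
#' ceiling (so accurate from the start that no improvement is measurable)
#' or at floor (unable to learn) are flagged; whether to exclude them is
#' left to the pipeline.
#'
#' @param ie_tbl Per-block IE tibble of the learning condition (see
#'   [block_inverse_efficiency()]).
#' @param curve The fitted [fit_learning_curve()] for the same subject.
#' @param ceiling_accuracy Mean accuracy at or above which a subject is a
#'   ceiling performer.
#' @param floor_accuracy Mean accuracy at or below which a subject is a
#'   floor performer (non-learner).
#' @return One-row tibble with `mean_accuracy`, `learning_rate`,
#'   `at_ceiling`, `at_floor`, `learner`.
#' @export
flag_performance <- function(ie_tbl, curve, ceiling_accuracy = 0.97,
                             floor_accuracy = 0.60) {
  acc <- mean(ie_tbl$accuracy)
  at_ceiling <- acc >= ceiling_accuracy
  at_floor <- acc <= floor_accuracy || curve$b <= 0
  tibble(
    mean_accuracy = acc,
    learning_rate = curve$b,
    at_ceiling = at_ceiling,
    at_floor = at_floor,
    learner = !at_ceiling && !at_floor
  )
}
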