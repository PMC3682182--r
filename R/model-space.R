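#' Run-weight profiles for a type of coupling change
#'
#' The four rest runs (day 1 pre/post, day 2 pre/post) are weighted by fixed
#' profiles encoding when a coupling change is expressed:
#' * `adaptation` — non-specific within-day change (the effect of time in
#'   the scanner), weights `[0 1 0 1]`;
#' * `learning` — adaptation plus a change expressed only directly after
#'   learning on day 1, weights `[0 1 0 0]`;
#' * `consolidation` — adaptation plus a learning change that persists at
#'   half its level on day 2, weights `[0 2 1 1]`.
#'
#' Learning and consolidation models therefore carry two bilinear parameters
#' per modulated connection (one per profile).
#'
#' @param change_type One of `"adaptation"`, `"learning"`, `"consolidation"`.
#' @return Named list of length-4 run-weight vectors.
#' @export
#' @examples
#' modulator_weights("consolidation")
modulator_weights <- function(change_type) {
  switch(
    change_type,
    adaptation = list(adaptation = c(0, 1, 0, 1)),
    learning = list(adaptation = c(0, 1, 0, 1),
                    learning = c(0, 1, 0, 0)),
    consolidation = list(adaptation = c(0, 1, 0, 1),
                         consolidation = c(0, 2, 1, 1)),
    abort_restdcm(sprintf("unknown change type '%s'", change_type),
                  "restdcm_parameter_error")
  )
}

#' Build the ten-model space of coupling-change hypotheses
#'
#' Crosses the three change types (adaptation, learning, consolidation) with
#' the three connection patterns (forward, backward, bidirectional) and adds
#' the null model of no change. The three null variants for the different
#' architectures are structurally identical and are deduplicated, leaving
#' ten unique models in a fixed, reproducible order.
#'
#' @return Named list of ten [dcm_spec()] objects: `null`, `A-fwd`, `A-bwd`,
#'   `A-both`, `L-fwd`, `L-bwd`, `L-both`, `C-fwd`, `C-bwd`, `C-both`.
#' @export
#' @examples
#' names(build_model_space())
build_model_space <- function() {
  patterns <- list(fwd = "forward", bwd = "backward",
                   both = c("forward", "backward"))
  types <- c(null = "null", A = "adaptation", L = "learning",
             C = "consolidation")
  specs <- list()
  for (ti in names(types)) {
    for (pi in names(patterns)) {
      type <- types[[ti]]
      if (type == "null") {
        # no modulators: architecture label is vacuous
        sp <- dcm_spec("null")
      } else {
        sp <- dcm_spec(paste0(ti, "-", pi),
                       connections = patterns[[pi]],
                       modulators = modulator_weights(type))
      }
      specs[[length(specs) + 1L]] <- sp
    }
  }
  # deduplicate by structural equality (name excluded)
  keys <- vapply(specs, function(s) {
    paste(paste(sort(s$connections), collapse = ","),
          paste(names(s$modulators),
                vapply(s$modulators, paste, "", collapse = " "),
                collapse = ";"),
          sep = "|")
  }, "")
  specs <- specs[!duplicated(keys)]
  names(specs) <- vapply(specs, function(s) s$name, "")
  stopifnot(!anyDuplicated(names(specs)))
  specs
}

#' Bayes factor from a log-evidence difference
#'
#' @param delta_log_ev Difference of log evidences (nats).
#' @return `exp(delta_log_ev)`: the evidence ratio. A difference of 3
#'   corresponds to odds of about 20:1.
#' @export
#' @examples
#' bayes_factor(3) # ~20.1
bayes_factor <- function(delta_log_ev) {
  if (!is.numeric(delta_log_ev) || any(!is.finite(delta_log_ev))) {
    abort_restdcm("`delta_log_ev` must be finite", "restdcm_parameter_error")
  }
  exp(delta_log_ev)
}

#' Fixed-effects Bayesian model selection
#'
#' Sums log evidences over subjects (equivalent to multiplying subject-level
#' marginal likelihoods: the fixed-effects assumption that a single model
#' generated every subject's data), reports evidences relative to the
#' weakest model, the winning model, per-subject winners, and whether the
#' winner beats the runner-up by the log-evidence criterion.
#'
#' @param log_ev Either a numeric matrix (subjects x models, column names =
#'   model labels) or a tidy data frame with columns `subject`, `model`,
#'   `log_evidence`.
#' @param criterion Log-evidence difference required to declare a winner
#'   (default 3, i.e. a Bayes factor of about 20:1).
#' @return An object of class `bms_result` with elements `summed`,
#'   `relative`, `winner`, `per_subject_winner`, `criterion_met`, `delta`,
#'   `log_ev` and `criterion`. Ties at the maximum are reported as multiple
#'   winners with `criterion_met = FALSE`.
#' @export
#' @examples
#' m <- matrix(c(0, 5, 1, 0, 6, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(NULL, c("null", "C-both", "A-fwd")))
#' fixed_effects_bms(m)
fixed_effects_bms <- function(log_ev, criterion = 3) {
  if (is.data.frame(log_ev)) {
    need <- c("subject", "model", "log_evidence")
    if (!all(need %in% names(log_ev))) {
      abort_restdcm("tidy input needs columns subject, model, log_evidence",
                    "restdcm_parameter_error")
    }
    wide <- tidyr::pivot_wider(
      log_ev[need], names_from = "model", values_from = "log_evidence"
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide$subject)
    log_ev <- m
  }
  if (!is.matrix(log_ev) || !all(is.finite(log_ev))) {
    abort_restdcm("`log_ev` must be a finite numeric matrix",
                  "restdcm_parameter_error")
  }
  if (is.null(colnames(log_ev))) {
    colnames(log_ev) <- paste0("model_", seq_len(ncol(log_ev)))
  }
  summed <- colSums(log_ev)
  relative <- summed - min(summed)
  ord <- order(summed, decreasing = TRUE)
  top <- summed[ord[1]]
  winners <- names(summed)[summed == top]
  delta <- if (length(summed) > 1) top - summed[ord[2]] else Inf
  tie <- length(winners) > 1
  per_subject <- apply(log_ev, 1L, function(r) names(summed)[which.max(r)])
  structure(
    list(
      log_ev = log_ev,
      summed = summed,
      relative = relative,
      winner = winners,
      per_subject_winner = per_subject,
      delta = unname(delta),
      criterion = criterion,
      criterion_met = !tie && delta >= criterion,
      tie = tie
    ),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> fixed-effects Bayesian model selection\n")
  cat(sprintf("  %d subjects x %d models\n", nrow(x$log_ev), ncol(x$log_ev)))
  cat("  winner:", paste(x$winner, collapse = ", "),
      if (x$tie) "(tie)" else "", "\n")
  cat(sprintf("  delta log evidence vs runner-up: %.2f (criterion %.1f, %s)\n",
              x$delta, x$criterion,
              if (x$criterion_met) "met" else "not met"))
  invisible(x)
}
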