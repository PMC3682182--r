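#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic replay: cohort size,
#' scan and task design, ground-truth effect sizes, priors, filtering
#' cut-offs and behavioral screening thresholds. Any element can be
#' overridden; `yaml` path input is supported for scripted use.
#'
#' @param n_subjects Cohort size.
#' @param design A [task_design()].
#' @param scan A [scan_config()].
#' @param truth A [ground_truth()].
#' @param priors A [dcm_priors()].
#' @param task_cutoff,rest_cutoff High-pass cut-offs (s).
#' @param ceiling_accuracy,floor_accuracy Behavioral screening thresholds
#'   (see [flag_performance()]).
#' @param exclude_nonlearners Drop flagged subjects between the behavior
#'   and GLM stages?
#' @param models Model space for the DCM stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 11L,
                            design = task_design(),
                            scan = scan_config(),
                            truth = ground_truth(),
                            priors = dcm_priors(),
                            task_cutoff = 128,
                            rest_cutoff = 256,
                            ceiling_accuracy = 0.97,
                            floor_accuracy = 0.60,
                            exclude_nonlearners = TRUE,
                            models = build_model_space()) {
  structure(
    list(n_subjects = stopifnot_count(n_subjects, "n_subjects"),
         design = design, scan = scan, truth = truth, priors = priors,
         task_cutoff = task_cutoff, rest_cutoff = rest_cutoff,
         ceiling_accuracy = ceiling_accuracy,
         floor_accuracy = floor_accuracy,
         exclude_nonlearners = exclude_nonlearners,
         models = models),
    class = "pipeline_config"
  )
}

#' Read pipeline overrides from a YAML file
#'
#' Top-level keys `n_subjects`, `task_cutoff`, `rest_cutoff`,
#' `ceiling_accuracy`, `floor_accuracy`, `exclude_nonlearners` and the
#' nested blocks `scan`, `design`, `truth` (scalar fields only) override
#' the defaults of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  scan <- do.call(scan_config, y$scan %||% list())
  design <- do.call(task_design, y$design %||% list())
  truth <- do.call(ground_truth, y$truth %||% list())
  args <- y[setdiff(names(y), c("scan", "design", "truth"))]
  do.call(pipeline_config,
          c(list(design = design, scan = scan, truth = truth), args))
}

#' Run the full synthetic replay pipeline
#'
#' Simulates a cohort, then runs all analysis stages in order: behavioral
#' learning curves (with outlier exclusion and ceiling/floor screening),
#' first-level task GLM with the inverse-efficiency parametric modulator
#' and a group t-test, the day-by-time PPI screen, DCM fitting of the
#' ten-model space per subject, fixed-effects Bayesian model selection,
#' and the group coupling time-course under the winning model.
#'
#' @param config A [pipeline_config()].
#' @param seed Master seed; all stages derive their seeds from it.
#' @param out_dir Optional directory: if given, the report is written as
#'   `report.json` there (created if missing).
#' @param stages Character subset of
#'   `c("behavior", "glm", "ppi", "dcm")` to run after simulation.
#' @param verbose Print stage progress?
#' @return A list of class `pipeline_report` with per-stage results:
#'   `subjects` (tibble of per-subject behavioral summaries and inclusion),
#'   `glm` (group test), `ppi` (per-subject contrasts and group test),
#'   `bms` (a [fixed_effects_bms()] result), `coupling` (group mean and
#'   SEM per connection and run) and `meta` (seed, sizes, winner).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL,
                         stages = c("behavior", "glm", "ppi", "dcm"),
                         verbose = TRUE) {
  seed <- stopifnot_count(seed, "seed", min = 0L)
  say <- function(...) if (verbose) message(sprintf(...))
  n <- config$n_subjects
  scan <- config$scan
  design <- config$design
  truth <- config$truth

  # --- simulate ------------------------------------------------------------
  say("[simulate] %d subjects (seed %d)", n, seed)
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    start <- design$conditions[(s %% 2L) + 1L]
    subjects[[s]] <- list(
      id = s, start = start,
      behavior = gen_behavior(design, truth,
                              seed = derive_seed(seed, s, 1L),
                              subject = s, start_condition = start),
      rest = gen_rest_bold(truth, scan, seed = derive_seed(seed, s, 2L)),
      task = if ("glm" %in% stages) {
        gen_task_bold(design, truth, seed = derive_seed(seed, s, 3L),
                      scan = scan, start_condition = start)
      }
    )
  }

  # --- behavior ------------------------------------------------------------
  curves <- list(); subj_tbl <- list()
  for (s in seq_len(n)) {
    tt <- exclude_rt_outliers(subjects[[s]]$behavior)
    ie <- block_inverse_efficiency(tt)
    curve <- fit_learning_curve(ie$ie, excluded_trials = n_excluded(tt))
    flags <- flag_performance(ie, curve,
                              ceiling_accuracy = config$ceiling_accuracy,
                              floor_accuracy = config$floor_accuracy)
    curves[[s]] <- curve
    subj_tbl[[s]] <- dplyr::bind_cols(
      tibble(subject = s, a = curve$a, b = curve$b, rss = curve$rss,
             excluded_trials = curve$excluded_trials),
      flags
    )
  }
  subj_tbl <- dplyr::bind_rows(subj_tbl)
  included <- if (config$exclude_nonlearners) {
    subj_tbl$subject[subj_tbl$learner]
  } else {
    subj_tbl$subject
  }
  say("[behavior] %d/%d subjects retained as learners", length(included), n)

  # --- task GLM ------------------------------------------------------------
  glm_res <- NULL
  if ("glm" %in% stages) {
    onset_cache <- list()
    betas <- purrr::map_dbl(included, function(s) {
      st <- subjects[[s]]$start
      if (is.null(onset_cache[[st]])) {
        onset_cache[[st]] <<- task_block_onsets(design, scan,
                                                start_condition = st)
      }
      X <- build_design_matrix(onset_cache[[st]], curves[[s]]$ie_fitted,
                               scan, cutoff = config$task_cutoff)
      task <- subjects[[s]]$task
      y_full <- task[order(task$run, task$volume), ][[truth$regions[1]]]
      y <- y_full[attr(X, "keep_rows")]
      fit <- fit_first_level(y, X)
      fit$contrasts$estimate[fit$contrasts$contrast == "ie"]
    })
    glm_res <- list(betas = tibble(subject = included, beta_ie = betas),
                    group = group_ttest(betas))
    say("[glm] group IE-modulator t = %.2f (p = %.3g)",
        glm_res$group$t, glm_res$group$p)
  }

  # --- PPI -----------------------------------------------------------------
  ppi_res <- NULL
  if ("ppi" %in% stages) {
    contr <- purrr::map(included, function(s) {
      sl <- run_coupling_slope(subjects[[s]]$rest, truth$regions[1],
                               truth$regions[2], tr = scan$tr,
                               cutoff = config$rest_cutoff,
                               discard = scan$discard_initial)
      dplyr::bind_cols(tibble(subject = s), factorial_contrasts(sl))
    }) %>% dplyr::bind_rows()
    ppi_res <- list(contrasts = contr,
                    group = group_interaction_test(contr$interaction))
    say("[ppi] group day-by-time interaction t = %.2f (p = %.3g)",
        ppi_res$group$t, ppi_res$group$p)
  }

  # --- DCM + BMS -----------------------------------------------------------
  bms <- NULL; coupling <- NULL; fits <- NULL
  if ("dcm" %in% stages) {
    log_ev <- list(); fits <- list()
    for (s in included) {
      ms <- fit_model_space(subjects[[s]]$rest, models = config$models,
                            priors = config$priors, tr = scan$tr,
                            cutoff = config$rest_cutoff,
                            discard = scan$discard_initial,
                            regions = truth$regions)
      fits[[as.character(s)]] <- ms$fits
      log_ev[[as.character(s)]] <- dplyr::bind_cols(
        tibble(subject = s), ms$log_ev
      )
      say("[dcm] subject %d: best model %s", s,
          ms$log_ev$model[which.max(ms$log_ev$log_evidence)])
    }
    log_ev <- dplyr::bind_rows(log_ev)
    bms <- fixed_effects_bms(log_ev)
    say("[bms] winner: %s (delta %.2f, criterion %s)",
        paste(bms$winner, collapse = "/"), bms$delta,
        if (bms$criterion_met) "met" else "not met")
    win <- bms$winner[1]
    coupling <- purrr::map(names(fits), function(s) {
      dplyr::bind_cols(tibble(subject = as.integer(s)),
                       coupling_timecourse(fits[[s]][[win]]))
    }) %>%
      dplyr::bind_rows() %>%
      group_by(connection, run) %>%
      summarise(mean_change = mean(change),
                sem = stats::sd(change) / sqrt(dplyr::n()),
                .groups = "drop")
  }

  report <- structure(
    list(
      subjects = subj_tbl,
      included = included,
      curves = curves,
      glm = glm_res,
      ppi = ppi_res,
      bms = bms,
      coupling = coupling,
      meta = list(seed = seed, n_subjects = n,
                  n_included = length(included),
                  rest_volumes = scan$rest_volumes,
                  winner = if (!is.null(bms)) bms$winner else NULL,
                  criterion_met = if (!is.null(bms)) bms$criterion_met
                                  else NULL)
    ),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writable <- list(
      meta = report$meta,
      subjects = report$subjects,
      glm_group = if (!is.null(glm_res)) glm_res$group,
      ppi_group = if (!is.null(ppi_res)) ppi_res$group,
      bms = if (!is.null(bms)) {
        list(summed = as.list(bms$summed), relative = as.list(bms$relative),
             winner = bms$winner, per_subject_winner = bms$per_subject_winner,
             delta = bms$delta, criterion_met = bms$criterion_met)
      },
      coupling = coupling
    )
    jsonlite::write_json(writable, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d subjects simulated, %d included\n",
              x$meta$n_subjects, x$meta$n_included))
  if (!is.null(x$glm)) {
    cat(sprintf("  group IE-modulator t = %.2f (p = %.3g)\n",
                x$glm$group$t, x$glm$group$p))
  }
  if (!is.null(x$ppi)) {
    cat(sprintf("  group PPI interaction t = %.2f (p = %.3g)\n",
                x$ppi$group$t, x$ppi$group$p))
  }
  if (!is.null(x$bms)) {
    cat(sprintf("  BMS winner: %s (delta %.2f, criterion %s)\n",
                paste(x$bms$winner, collapse = "/"), x$bms$delta,
                if (x$bms$criterion_met) "met" else "not met"))
  }
  invisible(x)
}
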