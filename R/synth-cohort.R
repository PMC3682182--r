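#' Write / read a ground-truth JSON sidecar
#'
#' The sidecar records every generative parameter of a synthetic subject,
#' including the run-weight rows of the true change model, at full numeric
#' precision so that write -> read round-trips losslessly.
#'
#' @param truth A [ground_truth()].
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a [ground_truth()].
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    a_forward = truth$a_forward, a_backward = truth$a_backward,
    a_self = truth$a_self,
    model = list(
      name = truth$spec$name,
      connections = as.list(truth$spec$connections),
      modulators = purrr::map(truth$spec$modulators, as.numeric)
    ),
    b = if (is.null(truth$b)) NULL else {
      list(values = as.numeric(truth$b),
           modulators = rownames(truth$b),
           connections = colnames(truth$b))
    },
    sigma_z = truth$sigma_z, obs_noise_sd = truth$obs_noise_sd,
    drift_sd = truth$drift_sd, ar_half_life = truth$ar_half_life,
    regions = as.list(truth$regions),
    behavior = truth$behavior, task = truth$task
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- dcm_spec(
    j$model$name,
    connections = as.character(unlist(j$model$connections)),
    modulators = purrr::map(j$model$modulators, as.numeric)
  )
  b <- NULL
  if (!is.null(j$b)) {
    b <- matrix(as.numeric(j$b$values),
                nrow = length(j$b$modulators),
                dimnames = list(j$b$modulators, j$b$connections))
  }
  ground_truth(
    a_forward = j$a_forward, a_backward = j$a_backward, a_self = j$a_self,
    spec = spec, b = b, sigma_z = j$sigma_z, obs_noise_sd = j$obs_noise_sd,
    drift_sd = j$drift_sd, ar_half_life = j$ar_half_life,
    regions = as.character(unlist(j$regions)),
    behavior = as.list(j$behavior), task = as.list(j$task)
  )
}

#' Generate a full synthetic cohort on disk
#'
#' Writes, for every subject, a behavior TSV, a rest-BOLD TSV, a task-BOLD
#' TSV and a ground-truth JSON sidecar under `sub-XX/` directories.
#' Per-subject seeds are derived reproducibly from the master seed, so the
#' same call produces byte-identical output.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param out_dir Output directory (created if missing). Refuses to write
#'   into an existing non-empty directory unless `overwrite = TRUE`.
#' @param master_seed Integer master seed.
#' @param design A [task_design()].
#' @param scan A [scan_config()].
#' @param truth A [ground_truth()] shared by all subjects.
#' @param overwrite Allow writing into a non-empty directory?
#' @return Tibble manifest (subject, start condition, seeds, file paths),
#'   invisibly.
#' @export
gen_cohort <- function(n_subjects, out_dir, master_seed = 1L,
                       design = task_design(), scan = scan_config(),
                       truth = ground_truth(), overwrite = FALSE) {
  n_subjects <- stopifnot_count(n_subjects, "n_subjects")
  master_seed <- stopifnot_count(master_seed, "master_seed", min = 0L)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    abort_restdcm(
      sprintf("output directory '%s' is not empty; use overwrite = TRUE",
              out_dir),
      "restdcm_io_error"
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sdir <- file.path(out_dir, sprintf("sub-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    start <- design$conditions[(s %% 2L) + 1L]
    seeds <- c(behavior = derive_seed(master_seed, s, 1L),
               rest = derive_seed(master_seed, s, 2L),
               task = derive_seed(master_seed, s, 3L))
    beh <- gen_behavior(design, truth, seed = seeds[["behavior"]],
                        subject = s, start_condition = start)
    rest <- gen_rest_bold(truth, scan, seed = seeds[["rest"]])
    task <- gen_task_bold(design, truth, scan, seed = seeds[["task"]],
                          start_condition = start)
    paths <- c(behavior = file.path(sdir, "behavior.tsv"),
               rest = file.path(sdir, "rest_bold.tsv"),
               task = file.path(sdir, "task_bold.tsv"),
               truth = file.path(sdir, "ground_truth.json"))
    readr::write_tsv(beh, paths[["behavior"]])
    readr::write_tsv(rest, paths[["rest"]])
    readr::write_tsv(task, paths[["task"]])
    write_ground_truth(truth, paths[["truth"]])
    manifest[[s]] <- tibble(
      subject = s, start_condition = start,
      seed_behavior = seeds[["behavior"]], seed_rest = seeds[["rest"]],
      seed_task = seeds[["task"]],
      behavior_tsv = paths[["behavior"]], rest_tsv = paths[["rest"]],
      task_tsv = paths[["task"]], truth_json = paths[["truth"]]
    )
  }
  invisible(dplyr::bind_rows(manifest))
}
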