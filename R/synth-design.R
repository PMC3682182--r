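#' Task design of the motion-coherence learning experiment
#'
#' Two interleaved conditions — a random-dot motion-coherence discrimination
#' task and a static control task — presented in strictly alternating blocks
#' of trials, spread over the task runs. The defaults mirror a rapid
#' perceptual-learning session: 25 blocks of 16 trials per condition
#' (800 trials in total), 0.3 s stimulus presentation, 1.5 s response
#' window, 20% motion coherence.
#'
#' @param n_blocks_per_condition Blocks per condition.
#' @param trials_per_block Trials per block.
#' @param conditions Labels of the two conditions (learning task first).
#' @param stimulus_duration,response_window Seconds.
#' @param coherence Fraction of coherently moving dots.
#' @return A list of class `task_design`.
#' @export
#' @examples
#' task_design()
task_design <- function(n_blocks_per_condition = 25L,
                        trials_per_block = 16L,
                        conditions = c("motion", "control"),
                        stimulus_duration = 0.3,
                        response_window = 1.5,
                        coherence = 0.20) {
  n_blocks_per_condition <- stopifnot_count(n_blocks_per_condition,
                                            "n_blocks_per_condition")
  trials_per_block <- stopifnot_count(trials_per_block, "trials_per_block")
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    abort_restdcm("`conditions` must be two distinct labels",
                  "restdcm_parameter_error")
  }
  stopifnot_scalar_number(stimulus_duration, "stimulus_duration",
                          positive = TRUE)
  stopifnot_scalar_number(response_window, "response_window", positive = TRUE)
  stopifnot_scalar_number(coherence, "coherence", positive = TRUE)
  structure(
    list(n_blocks_per_condition = n_blocks_per_condition,
         trials_per_block = trials_per_block,
         conditions = conditions,
         stimulus_duration = stimulus_duration,
         response_window = response_window,
         coherence = coherence),
    class = "task_design"
  )
}

#' Scan acquisition configuration
#'
#' @param tr Repetition time (s).
#' @param rest_volumes Volumes per resting-state run.
#' @param task_volumes Volumes per task run.
#' @param discard_initial Initial volumes of every run discarded before
#'   analysis (T1 equilibration).
#' @param n_rest_runs Rest runs, ordered day1-pre, day1-post, day2-pre,
#'   day2-post.
#' @param n_task_runs Task runs.
#' @return A list of class `scan_config`.
#' @export
#' @examples
#' scan_config()
scan_config <- function(tr = 2.176, rest_volumes = 276L, task_volumes = 246L,
                        discard_initial = 5L, n_rest_runs = 4L,
                        n_task_runs = 5L) {
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  rest_volumes <- stopifnot_count(rest_volumes, "rest_volumes")
  task_volumes <- stopifnot_count(task_volumes, "task_volumes")
  discard_initial <- stopifnot_count(discard_initial, "discard_initial",
                                     min = 0L)
  n_rest_runs <- stopifnot_count(n_rest_runs, "n_rest_runs")
  n_task_runs <- stopifnot_count(n_task_runs, "n_task_runs")
  if (discard_initial >= min(rest_volumes, task_volumes)) {
    abort_restdcm("`discard_initial` must be smaller than the run length",
                  "restdcm_parameter_error")
  }
  structure(
    list(tr = tr, rest_volumes = rest_volumes, task_volumes = task_volumes,
         discard_initial = discard_initial, n_rest_runs = n_rest_runs,
         n_task_runs = n_task_runs),
    class = "scan_config"
  )
}

#' Ground truth of a synthetic subject
#'
#' Bundles the generative parameters of one simulated subject: the average
#' coupling matrix, the bilinear coupling changes with their run-weight
#' profiles (by default the consolidation pattern on both connections),
#' noise and drift levels for the rest runs, the behavioral learning curve,
#' and the task-evoked response model.
#'
#' The default effect sizes are chosen so that the consolidation pattern is
#' recoverable by model comparison on single-subject rest data without being
#' trivially large; all of them are exposed here rather than hard-coded.
#'
#' @param a_forward,a_backward Average between-region coupling (Hz),
#'   region 1 (hippocampus) -> region 2 (striatum) and back.
#' @param a_self Self-connection (Hz, negative).
#' @param spec A [dcm_spec()] giving the true change model (default the
#'   bidirectional consolidation model). Use the null spec and `b = NULL`
#'   for a no-change subject.
#' @param b Bilinear parameter matrix (modulators x connections, Hz)
#'   matching `spec`; `NULL` for the null spec.
#' @param sigma_z Endogenous neuronal fluctuation SD (a.u.).
#' @param obs_noise_sd Observation noise SD (percent signal change).
#' @param drift_sd SD of the random amplitudes on the three slowest DCT
#'   drift components (percent signal change).
#' @param ar_half_life Correlation half-life (s) of the endogenous
#'   fluctuations.
#' @param regions Region names, seed region first.
#' @param behavior Named list of behavioral parameters: `ie_amplitude` (a,
#'   s), `ie_asymptote` (s), `learning_rate` (b, per block), `rt_sd` (s),
#'   `acc_start`, `acc_asymptote`, `control_accuracy`, `control_rt_mean`
#'   (s), `control_rt_sd` (s), `miss_rate`.
#' @param task Named list of task-BOLD parameters: `motion_amp`,
#'   `control_amp` (percent), `ie_gain` (percent per centered IE unit in the
#'   learning region), `noise_sd`, `drift_sd` (percent).
#' @return A list of class `ground_truth`.
#' @export
#' @examples
#' tr <- ground_truth()
#' tr$spec$name
ground_truth <- function(a_forward = 0.10, a_backward = 0.10, a_self = -0.5,
                         spec = NULL, b = NULL,
                         sigma_z = 0.05, obs_noise_sd = 0.05,
                         drift_sd = 0.4, ar_half_life = 2,
                         regions = c("hippocampus", "striatum"),
                         behavior = list(), task = list()) {
  if (is.null(spec)) {
    spec <- build_model_space()[["C-both"]]
    if (is.null(b)) {
      b <- matrix(c(0.04, 0.04, 0.15, 0.15), nrow = 2L, byrow = TRUE,
                  dimnames = list(c("adaptation", "consolidation"),
                                  c("forward", "backward")))
    }
  }
  if (length(spec$modulators) > 0 && is.null(b)) {
    abort_restdcm("`b` is required for a non-null true model",
                  "restdcm_parameter_error")
  }
  behavior_defaults <- list(
    ie_amplitude = 0.7, ie_asymptote = 0.6, learning_rate = 0.15,
    rt_sd = 0.10, acc_start = 0.65, acc_asymptote = 0.92,
    control_accuracy = 0.99, control_rt_mean = 0.5, control_rt_sd = 0.08,
    miss_rate = 0.01
  )
  task_defaults <- list(motion_amp = 1.0, control_amp = 1.0, ie_gain = 0.8,
                        noise_sd = 0.3, drift_sd = 0.5)
  behavior <- utils::modifyList(behavior_defaults, behavior)
  task <- utils::modifyList(task_defaults, task)
  if (behavior$learning_rate < 0) {
    abort_restdcm("behavioral learning rate must be >= 0",
                  "restdcm_parameter_error")
  }
  for (nm in c("ie_amplitude", "ie_asymptote", "control_rt_mean")) {
    if (behavior[[nm]] < 0 ||
        (nm != "ie_amplitude" && behavior[[nm]] <= 0)) {
      abort_restdcm(sprintf("behavioral parameter `%s` must be positive", nm),
                    "restdcm_parameter_error")
    }
  }
  if (behavior$rt_sd < 0 || behavior$control_rt_sd < 0) {
    abort_restdcm("RT standard deviations must be >= 0",
                  "restdcm_parameter_error")
  }
  if (sigma_z < 0 || obs_noise_sd < 0 || drift_sd < 0) {
    abort_restdcm("noise SDs must be >= 0", "restdcm_parameter_error")
  }
  truth <- structure(
    list(a_forward = a_forward, a_backward = a_backward, a_self = a_self,
         spec = spec, b = b, sigma_z = sigma_z, obs_noise_sd = obs_noise_sd,
         drift_sd = drift_sd, ar_half_life = ar_half_life, regions = regions,
         behavior = behavior, task = task),
    class = "ground_truth"
  )
  # the run-wise effective matrices must all be stable
  pars <- truth_dcm_params(truth)
  for (r in 1:4) effective_matrix(pars, spec, r)
  truth
}

# dcm_params view of a ground truth (for simulation)
truth_dcm_params <- function(truth) {
  dcm_params(a_forward = truth$a_forward, a_backward = truth$a_backward,
             a_self = truth$a_self, b = truth$b, sigma_z = truth$sigma_z,
             sigma_obs = truth$obs_noise_sd)
}
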