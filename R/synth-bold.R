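#' Generate four rest runs of two-region BOLD for one subject
#'
#' Simulates the bilinear neuronal model whose inter-regional coupling
#' follows the subject's true change pattern across the four rest runs,
#' passes it through the full nonlinear balloon hemodynamics
#' ([simulate_dcm()]), and adds a slow drift (the three lowest-frequency
#' DCT components with random amplitudes, removable by the 256-s high-pass)
#' plus white observation noise.
#'
#' @param truth A [ground_truth()].
#' @param scan A [scan_config()].
#' @param seed Integer RNG seed.
#' @return Tibble with columns `run` (1..4), `volume` (0-based) and one
#'   column per region (percent signal change).
#' @export
#' @examples
#' y <- gen_rest_bold(ground_truth(), scan_config(rest_volumes = 60), seed = 1)
#' dplyr::count(y, run)
gen_rest_bold <- function(truth, scan, seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(scan, "scan_config"))
  seed <- stopifnot_count(seed, "seed", min = 0L)
  params <- truth_dcm_params(truth)
  y <- simulate_dcm(params, truth$spec, scan, seed = seed,
                    ar_half_life = truth$ar_half_life,
                    regions = truth$regions)
  # simulate_dcm seeded the RNG; drift and observation noise continue the
  # same stream, so the whole record is a deterministic function of `seed`
  n_vol <- scan$rest_volumes
  dct3 <- dct_highpass_basis(n_vol, scan$tr,
                             cutoff = 2 * n_vol * scan$tr / 3 - 1e-9)
  dct3 <- dct3[, seq_len(min(3L, ncol(dct3))), drop = FALSE]
  for (r in sort(unique(y$run))) {
    ix <- which(y$run == r)
    for (reg in truth$regions) {
      drift <- as.numeric(dct3 %*% rnorm(ncol(dct3), 0, truth$drift_sd))
      noise <- rnorm(length(ix), 0, truth$obs_noise_sd)
      y[[reg]][ix] <- y[[reg]][ix] + drift + noise
    }
  }
  y
}

#' Generate five task runs of two-region BOLD for one subject
#'
#' Builds the same convolved block regressors that the first-level GLM
#' uses: the learning region (region 1, hippocampus-like) responds to
#' motion blocks with an evoked amplitude that scales linearly with the
#' subject's fitted inverse efficiency (gain `task$ie_gain`), while the
#' control region responds to both conditions without learning modulation.
#' Slow DCT drift and white noise are added.
#'
#' @param design A [task_design()].
#' @param truth A [ground_truth()].
#' @param scan A [scan_config()].
#' @param seed Integer RNG seed.
#' @param start_condition Condition of the first block (match
#'   [gen_behavior()] for the same subject).
#' @return Tibble with columns `run` (1..5), `volume` (0-based) and one
#'   column per region.
#' @export
gen_task_bold <- function(design, truth, scan, seed,
                          start_condition = "motion") {
  stopifnot(inherits(design, "task_design"), inherits(truth, "ground_truth"),
            inherits(scan, "scan_config"))
  seed <- stopifnot_count(seed, "seed", min = 0L)
  set.seed(seed)
  tk <- truth$task
  bh <- truth$behavior
  onsets <- task_block_onsets(design, scan, start_condition = start_condition)
  x <- seq_len(design$n_blocks_per_condition)
  ie_fitted <- bh$ie_asymptote + bh$ie_amplitude * exp(-bh$learning_rate * x)
  n_vol <- scan$task_volumes
  dct3 <- dct_highpass_basis(n_vol, scan$tr,
                             cutoff = 2 * n_vol * scan$tr / 3 - 1e-9)
  dct3 <- dct3[, seq_len(min(3L, ncol(dct3))), drop = FALSE]
  out <- vector("list", scan$n_task_runs)
  for (r in seq_len(scan$n_task_runs)) {
    on_r <- onsets[onsets$run == r, ]
    blocks_r <- on_r$block[on_r$condition == "motion"]
    ie_c <- setNames(ie_fitted[blocks_r] - mean(ie_fitted[blocks_r]),
                     blocks_r)
    Xr <- task_regressors(on_r, ie_c, scan)
    sig1 <- tk$motion_amp * Xr[, "motion"] + tk$ie_gain * Xr[, "motion_ie"]
    sig2 <- tk$motion_amp * Xr[, "motion"] + tk$control_amp * Xr[, "control"]
    mk <- function(sig) {
      sig + as.numeric(dct3 %*% rnorm(ncol(dct3), 0, tk$drift_sd)) +
        rnorm(n_vol, 0, tk$noise_sd)
    }
    y <- cbind(mk(sig1), mk(sig2))
    colnames(y) <- truth$regions
    out[[r]] <- dplyr::bind_cols(
      tibble(run = r, volume = 0:(n_vol - 1L)),
      as_tibble(y)
    )
  }
  dplyr::bind_rows(out)
}
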