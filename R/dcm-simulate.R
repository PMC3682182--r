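#' Simulate four rest runs from the bilinear neuronal + balloon model
#'
#' Integrates `dz/dt = A_r z + w(t)` per run by Euler--Maruyama on a fine
#' grid, passes each region's neuronal activity through the full nonlinear
#' balloon cascade, and samples the BOLD output at the TR. Endogenous
#' fluctuations `w(t)` are white by default or a stationary AR(1) process
#' with the given correlation half-life; their low-frequency spectral
#' density is `sigma_z^2` in either case. States are re-initialized and
#' burned in at the start of every run (runs are separate acquisitions).
#' Observation noise is *not* added here (see [gen_rest_bold()]).
#'
#' @param params A [dcm_params()] (noise SD `sigma_z` taken from it).
#' @param spec A [dcm_spec()] describing the run-specific coupling changes.
#' @param scan A [scan_config()].
#' @param seed Integer RNG seed.
#' @param dt Integration step (s), at most 0.1.
#' @param ar_half_life Correlation half-life (s) of the AR(1) neuronal
#'   innovations; `NULL` or 0 for white noise.
#' @param burn_s Burn-in (s) discarded before the first sampled volume.
#' @param regions Column names of the two regions.
#' @return Tibble with columns `run`, `volume` (0-based) and one column per
#'   region (percent signal change, noise-free).
#' @export
#' @examples
#' y <- simulate_dcm(dcm_params(), build_model_space()[["null"]],
#'                   scan_config(rest_volumes = 40), seed = 1)
#' dplyr::count(y, run)
simulate_dcm <- function(params, spec, scan = scan_config(), seed = 1L,
                         dt = 0.05, ar_half_life = NULL, burn_s = 32,
                         regions = c("region_1", "region_2")) {
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (dt > 0.1) {
    abort_restdcm("integration step `dt` must be <= 0.1 s",
                  "restdcm_parameter_error")
  }
  rho <- 0
  if (!is.null(ar_half_life) && ar_half_life > 0) {
    rho <- exp(-dt * log(2) / ar_half_life)
  }
  n_runs <- scan$n_rest_runs
  n_vols <- scan$rest_volumes
  burn_steps <- ceiling(burn_s / dt)
  n_steps <- burn_steps + ceiling((n_vols - 1) * scan$tr / dt) + 2L
  hemo <- params$hemo
  hv <- c(hemo$kappa, hemo$gamma, hemo$tau, hemo$alpha, hemo$E0, hemo$V0)
  set.seed(seed)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    Aeff <- tryCatch(
      effective_matrix(params, spec, run = r),
      restdcm_stability_error = function(e) {
        abort_restdcm(
          sprintf("run %d: %s", r, conditionMessage(e)),
          "restdcm_stability_error"
        )
      }
    )
    eps <- matrix(rnorm(n_steps * 2L), n_steps, 2L)
    y <- balloon_simulate_cpp(Aeff, eps, params$sigma_z, rho, dt,
                              scan$tr, n_vols, burn_steps, hv)
    colnames(y) <- regions
    out[[r]] <- dplyr::bind_cols(
      tibble(run = r, volume = 0:(n_vols - 1L)),
      as_tibble(y)
    )
  }
  dplyr::bind_rows(out)
}
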