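#' Linearized balloon hemodynamics
#'
#' First-order Taylor expansion of the balloon cascade around its resting
#' fixed point (s = 0, f = v = q = 1), giving a linear four-state system per
#' region (vasodilatory signal, flow, volume and deoxyhemoglobin deviations)
#' driven by neuronal activity, with a linear BOLD read-out in percent
#' signal change. This is the observation model used by the state-space
#' inversion; for small endogenous fluctuations its impulse response closely
#' matches the full nonlinear cascade.
#'
#' @param params A [dcm_params()] (only its `hemo` element is used) or a
#'   [hemo_params()] object.
#' @return A list with `H` (4x4 state matrix, states s, f, v, q), `b_in`
#'   (input vector mapping neuronal activity to the states), `c_out`
#'   (1x4 BOLD read-out row vector, percent) and `dc_gain` (steady-state
#'   percent BOLD per unit of sustained neuronal activity).
#' @export
#' @examples
#' op <- hemo_linear_approx(hemo_params())
#' op$dc_gain
hemo_linear_approx <- function(params) {
  h <- if (inherits(params, "hemo_params")) params else params$hemo
  kf <- (h$E0 + (1 - h$E0) * log(1 - h$E0)) / h$E0
  H <- matrix(c(
    -h$kappa, -h$gamma,            0,                         0,
     1,        0,                  0,                         0,
     0,        1 / h$tau,         -1 / (h$alpha * h$tau),     0,
     0,        kf / h$tau,        -(1 / h$alpha - 1) / h$tau, -1 / h$tau
  ), nrow = 4L, byrow = TRUE)
  c_out <- 100 * h$V0 *
    matrix(c(0, 0, h$k2 - h$k3, -(h$k1 + h$k2)), nrow = 1L)
  b_in <- c(1, 0, 0, 0)
  # steady state for unit sustained input: f = 1/gamma, v = alpha/gamma,
  # q = (kf - (1 - alpha)) / gamma
  dc_gain <- as.numeric(
    c_out %*% c(0, 1 / h$gamma, h$alpha / h$gamma,
                (kf - (1 - h$alpha)) / h$gamma)
  )
  list(H = H, b_in = b_in, c_out = c_out, dc_gain = dc_gain)
}

#' Discrete-time linear-Gaussian state space for one rest run
#'
#' Augments the two neuronal states with the four linearized hemodynamic
#' states per region and, when `innovation_half_life > 0`, two
#' Ornstein--Uhlenbeck innovation states modeling temporally smooth
#' endogenous fluctuations (12 latent states; 10 with white-noise driving).
#' The continuous-time system is discretized exactly at the TR via the
#' matrix exponential (Van Loan construction for the innovation
#' covariance, noise entering the innovation/neuronal states only) and
#' initialized at its stationary distribution.
#'
#' @param params A [dcm_params()].
#' @param spec A [dcm_spec()].
#' @param run Run index 1..4.
#' @param tr Sampling interval (s).
#' @param innovation_half_life Correlation half-life (s) of the endogenous
#'   fluctuations assumed by the model; 0 or `NULL` for white noise. The
#'   low-frequency spectral density of the neuronal drive is
#'   `params$sigma_z^2` in either case.
#' @return A list of class `dcm_state_space` with `Phi`, `Q`, `C`, `R`,
#'   `m0`, `P0`.
#' @export
dcm_state_space <- function(params, spec, run, tr = 2.176,
                            innovation_half_life = 2) {
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  Aeff <- effective_matrix(params, spec, run)
  lin <- hemo_linear_approx(params)
  colored <- !is.null(innovation_half_life) && innovation_half_life > 0
  lambda <- if (colored) log(2) / innovation_half_life else 0
  nreg <- 2L
  nh <- 4L
  off <- if (colored) 2L * nreg else nreg
  n <- off + nreg * nh
  Fm <- matrix(0, n, n)
  Fm[1:nreg, 1:nreg] <- Aeff
  if (colored) {
    Fm[1:nreg, nreg + 1:nreg] <- diag(nreg)
    Fm[nreg + 1:nreg, nreg + 1:nreg] <- -lambda * diag(nreg)
  }
  Cm <- matrix(0, nreg, n)
  for (r in seq_len(nreg)) {
    ix <- off + (r - 1L) * nh + seq_len(nh)
    Fm[ix, ix] <- lin$H
    Fm[ix, r] <- lin$b_in
    Cm[r, ix] <- lin$c_out
  }
  Lc <- matrix(0, n, n)
  if (colored) {
    diag(Lc)[nreg + 1:nreg] <- params$sigma_z^2 * lambda^2
  } else {
    diag(Lc)[1:nreg] <- params$sigma_z^2
  }
  d <- vanloan_discretize(Fm, Lc, tr)
  P0 <- dlyap_doubling(d$Phi, d$Q)
  structure(
    list(Phi = d$Phi, Q = d$Q, C = Cm,
         R = diag(params$sigma_obs^2, nreg),
         m0 = rep(0, n), P0 = P0),
    class = "dcm_state_space"
  )
}

#' Exact Gaussian marginal log-likelihood of a run
#'
#' Evaluates the marginal log density of the observed multivariate series
#' under a linear-Gaussian state-space model by the Kalman-filter
#' prediction-error decomposition. Runs are treated as independent
#' acquisitions: evaluate each run with its own state space and sum.
#'
#' @param y Numeric matrix, one row per time point, one column per region
#'   (a vector is taken as a single-region series).
#' @param ss A `dcm_state_space` (or any list with elements `Phi`, `Q`,
#'   `C`, `R`, `m0`, `P0`).
#' @return Scalar log-likelihood (nats); `-Inf` if the predicted innovation
#'   covariance loses positive definiteness.
#' @export
loglik_kalman <- function(y, ss) {
  if (is.vector(y)) y <- matrix(y, ncol = 1L)
  y <- as.matrix(y)
  if (ncol(y) != nrow(ss$C)) {
    abort_restdcm("`y` has wrong number of columns for the observation model",
                  "restdcm_parameter_error")
  }
  R <- as.matrix(ss$R)
  if (min(eigen(0.5 * (ss$P0 + t(ss$P0)), only.values = TRUE)$values) <
      -1e-8) {
    abort_restdcm("initial state covariance is not positive semidefinite",
                  "restdcm_numerical_error")
  }
  kalman_loglik_cpp(y, ss$Phi, ss$Q, ss$C, R, ss$m0, ss$P0)
}
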