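#' Balloon-model hemodynamic constants
#'
#' Standard constants of the nonlinear balloon/windkessel cascade linking
#' neuronal activity to the BOLD signal: vasodilatory signal decay `kappa`
#' (1/s), flow-dependent elimination `gamma` (1/s), venous transit time `tau`
#' (s), Grubb exponent `alpha`, resting oxygen extraction `E0` and resting
#' venous volume fraction `V0`. The observation coefficients are derived as
#' `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`.
#'
#' @param kappa,gamma,tau,alpha,E0,V0 Positive scalars; `alpha` in (0, 1).
#' @return A list of class `hemo_params`.
#' @export
#' @examples
#' hemo_params()
hemo_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                        alpha = 0.32, E0 = 0.32, V0 = 0.04) {
  for (nm in c("kappa", "gamma", "tau", "alpha", "E0", "V0")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (alpha >= 1) {
    abort_restdcm("`alpha` must lie in (0, 1)", "restdcm_parameter_error")
  }
  structure(
    list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
         E0 = E0, V0 = V0, k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2),
    class = "hemo_params"
  )
}

#' Parameters of the two-region bilinear neuronal model
#'
#' The latent neuronal state obeys `dz/dt = (A + sum_j m_j(r) B_j) z + w(t)`,
#' with fixed negative self-connections on the diagonal of `A` and free
#' between-region couplings (in Hz). `b` holds the bilinear (modulatory)
#' parameters, one per (modulator, connection) pair; each modulator `j`
#' carries a 4-vector of run weights `m_j(r)` stored in the model
#' specification (see [dcm_spec()]).
#'
#' @param a_forward Coupling region 1 -> region 2 (Hz).
#' @param a_backward Coupling region 2 -> region 1 (Hz).
#' @param a_self Self-connection, fixed and negative (Hz).
#' @param b Numeric matrix of bilinear parameters (modulators x connections)
#'   with column names among `"forward"`, `"backward"`, or `NULL` for none.
#' @param sigma_z Standard deviation of the endogenous neuronal fluctuations
#'   (a.u.).
#' @param sigma_obs Observation noise SD, length 1 (shared) or 2 (per
#'   region), in percent signal change.
#' @param hemo A [hemo_params()] object.
#' @return A list of class `dcm_params`.
#' @export
#' @examples
#' dcm_params(a_forward = 0.2, a_backward = 0.1)
dcm_params <- function(a_forward = 0.15, a_backward = 0.15, a_self = -0.5,
                       b = NULL, sigma_z = 0.1, sigma_obs = 0.1,
                       hemo = hemo_params()) {
  stopifnot_scalar_number(a_forward, "a_forward")
  stopifnot_scalar_number(a_backward, "a_backward")
  stopifnot_scalar_number(a_self, "a_self")
  if (a_self >= 0) {
    abort_restdcm("self-connections must be negative", "restdcm_parameter_error")
  }
  stopifnot_scalar_number(sigma_z, "sigma_z")
  if (sigma_z < 0) {
    abort_restdcm("`sigma_z` must be >= 0", "restdcm_parameter_error")
  }
  if (any(sigma_obs < 0)) {
    abort_restdcm("`sigma_obs` must be >= 0", "restdcm_parameter_error")
  }
  if (length(sigma_obs) == 1L) sigma_obs <- rep(sigma_obs, 2L)
  if (!is.null(b)) {
    b <- as.matrix(b)
    if (is.null(colnames(b)) ||
        !all(colnames(b) %in% c("forward", "backward"))) {
      abort_restdcm(
        "`b` must have column names among 'forward'/'backward'",
        "restdcm_parameter_error"
      )
    }
  }
  structure(
    list(a_forward = a_forward, a_backward = a_backward, a_self = a_self,
         b = b, sigma_z = sigma_z, sigma_obs = sigma_obs, hemo = hemo),
    class = "dcm_params"
  )
}

# average (run-independent) coupling matrix; convention: region 1 is the
# seed ("hippocampus-like") node, A[2, 1] is the forward connection 1 -> 2
a_matrix <- function(params) {
  matrix(c(params$a_self, params$a_forward,
           params$a_backward, params$a_self),
         nrow = 2L, ncol = 2L)
}

#' Specify one model of run-specific coupling changes
#'
#' A model names the connections whose strength is allowed to change across
#' the four rest runs and the parametric modulators expressing when the
#' change occurs. Each modulator is a 4-vector of run weights; the bilinear
#' parameter attached to a (modulator, connection) pair scales that weight
#' profile on that connection.
#'
#' @param name Model label.
#' @param connections Character subset of `c("forward", "backward")`; empty
#'   for the null model.
#' @param modulators Named list of length-4 numeric run-weight vectors
#'   (e.g. `list(adaptation = c(0, 1, 0, 1))`); empty for the null model.
#' @return A list of class `dcm_spec`.
#' @seealso [build_model_space()], [modulator_weights()]
#' @export
dcm_spec <- function(name, connections = character(),
                     modulators = list()) {
  if (!all(connections %in% c("forward", "backward"))) {
    abort_restdcm("unknown connection label", "restdcm_parameter_error")
  }
  if (length(modulators) > 0 &&
      (is.null(names(modulators)) ||
       !all(vapply(modulators, length, 1L) == 4L))) {
    abort_restdcm("modulators must be a named list of 4-vectors",
                  "restdcm_parameter_error")
  }
  if (length(modulators) > 0 && length(connections) == 0) {
    abort_restdcm("modulated model needs at least one connection",
                  "restdcm_parameter_error")
  }
  structure(
    list(name = name, connections = connections, modulators = modulators),
    class = "dcm_spec"
  )
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("<dcm_spec> ", x$name, "\n", sep = "")
  if (length(x$modulators) == 0) {
    cat("  null model: no coupling changes\n")
  } else {
    cat("  connections modulated:", paste(x$connections, collapse = ", "), "\n")
    for (nm in names(x$modulators)) {
      cat(sprintf("  %-14s weights [%s]\n", nm,
                  paste(x$modulators[[nm]], collapse = " ")))
    }
  }
  invisible(x)
}

# number of free bilinear parameters of a spec
n_bilinear <- function(spec) length(spec$connections) * length(spec$modulators)

#' Run-specific effective coupling matrix
#'
#' Computes `A_r = A + sum_j m_j(r) B_j`, where `B_j` places the bilinear
#' parameter `b[j, c]` on connection `c` and zeros elsewhere. Errors if the
#' resulting matrix has an eigenvalue with non-negative real part (an
#' unstable neuronal model).
#'
#' @param params A [dcm_params()] object whose `b` matrix has one row per
#'   modulator of `spec` and one column per modulated connection.
#' @param spec A [dcm_spec()].
#' @param run Run index in 1..4.
#' @param check_stability Error on instability? (default `TRUE`)
#' @return A 2x2 numeric matrix (Hz).
#' @export
#' @examples
#' sp <- build_model_space()[["C-both"]]
#' b <- matrix(0.1, 2, 2, dimnames = list(names(sp$modulators), sp$connections))
#' effective_matrix(dcm_params(b = b), sp, run = 2)
effective_matrix <- function(params, spec, run, check_stability = TRUE) {
  run <- stopifnot_count(run, "run")
  if (run > 4L) {
    abort_restdcm("`run` must lie in 1..4", "restdcm_parameter_error")
  }
  A <- a_matrix(params)
  idx <- list(forward = c(2L, 1L), backward = c(1L, 2L))
  if (length(spec$modulators) > 0) {
    b <- params$b
    if (is.null(b) || nrow(b) != length(spec$modulators) ||
        !all(spec$connections %in% colnames(b))) {
      abort_restdcm(
        "`params$b` does not match the modulators/connections of `spec`",
        "restdcm_parameter_error"
      )
    }
    for (j in seq_along(spec$modulators)) {
      w <- spec$modulators[[j]][run]
      for (con in spec$connections) {
        ij <- idx[[con]]
        A[ij[1], ij[2]] <- A[ij[1], ij[2]] + w * b[j, con]
      }
    }
  }
  if (check_stability) {
    ev <- eigen(A, only.values = TRUE)$values
    if (max(Re(ev)) >= 0) {
      abort_restdcm(
        sprintf("effective coupling matrix for run %d is unstable (max Re eigenvalue %.3f)",
                run, max(Re(ev))),
        "restdcm_stability_error"
      )
    }
  }
  A
}
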