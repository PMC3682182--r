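#' Priors for the DCM parameters
#'
#' Zero-mean Gaussian shrinkage priors on the average couplings and
#' bilinear parameters (Hz) and Gaussian priors on the log noise SDs.
#'
#' @param sd_a Prior SD of the between-region couplings (Hz).
#' @param sd_b Prior SD of the bilinear parameters (Hz).
#' @param mean_log_sigma_z,mean_log_sigma_obs Prior means of the log noise
#'   SDs.
#' @param sd_log_noise Prior SD of the log noise SDs.
#' @return A list of class `dcm_priors`.
#' @export
dcm_priors <- function(sd_a = 0.25, sd_b = 0.25,
                       mean_log_sigma_z = log(0.1),
                       mean_log_sigma_obs = log(0.1),
                       sd_log_noise = 1) {
  structure(
    list(sd_a = sd_a, sd_b = sd_b,
         mean_log_sigma_z = mean_log_sigma_z,
         mean_log_sigma_obs = mean_log_sigma_obs,
         sd_log_noise = sd_log_noise),
    class = "dcm_priors"
  )
}

# parameter vector layout for a given spec ----------------------------------

theta_template <- function(spec, priors) {
  nm <- c("a_forward", "a_backward")
  mean <- c(0, 0)
  sd <- c(priors$sd_a, priors$sd_a)
  if (length(spec$modulators) > 0) {
    for (j in names(spec$modulators)) {
      for (con in spec$connections) {
        nm <- c(nm, paste0("b_", j, "_", con))
        mean <- c(mean, 0)
        sd <- c(sd, priors$sd_b)
      }
    }
  }
  nm <- c(nm, "log_sigma_z", "log_sigma_obs_1", "log_sigma_obs_2")
  mean <- c(mean, priors$mean_log_sigma_z, rep(priors$mean_log_sigma_obs, 2))
  sd <- c(sd, rep(priors$sd_log_noise, 3))
  list(names = nm, mean = setNames(mean, nm), sd = setNames(sd, nm))
}

theta_to_params <- function(theta, spec, a_self = -0.5,
                            hemo = hemo_params()) {
  b <- NULL
  if (length(spec$modulators) > 0) {
    b <- matrix(NA_real_, nrow = length(spec$modulators),
                ncol = length(spec$connections),
                dimnames = list(names(spec$modulators), spec$connections))
    for (j in names(spec$modulators)) {
      for (con in spec$connections) {
        b[j, con] <- theta[[paste0("b_", j, "_", con)]]
      }
    }
  }
  dcm_params(
    a_forward = theta[["a_forward"]], a_backward = theta[["a_backward"]],
    a_self = a_self, b = b, sigma_z = exp(theta[["log_sigma_z"]]),
    sigma_obs = exp(c(theta[["log_sigma_obs_1"]],
                      theta[["log_sigma_obs_2"]])),
    hemo = hemo
  )
}

# per-run observation matrices: drop initial volumes, partial out constant
# and 256-s DCT drift basis
prepare_rest_runs <- function(rest, regions, tr, cutoff = 256,
                              discard = 5L) {
  runs <- sort(unique(rest$run))
  purrr::map(runs, function(r) {
    d <- rest[rest$run == r, ]
    d <- d[order(d$volume), ]
    keep <- seq_len(nrow(d)) > discard
    Y <- as.matrix(d[keep, regions])
    Z <- cbind(1, dct_highpass_basis(nrow(Y), tr, cutoff))
    Y - Z %*% qr.coef(qr(Z), Y)
  })
}

# negative log joint (likelihood + prior); large finite value when unstable
# or numerically degenerate so that optimizers can recover
neg_log_joint <- function(theta, Ylist, spec, priors, tr, a_self, hemo,
                          tmpl, innovation_half_life = 2) {
  theta <- setNames(theta, tmpl$names)
  params <- tryCatch(theta_to_params(theta, spec, a_self, hemo),
                     error = function(e) NULL)
  if (is.null(params)) return(1e10)
  # stability barrier across runs
  max_re <- -Inf
  for (r in seq_along(Ylist)) {
    A <- tryCatch(effective_matrix(params, spec, r, check_stability = FALSE),
                  error = function(e) NULL)
    if (is.null(A)) return(1e10)
    max_re <- max(max_re, max(Re(eigen(A, only.values = TRUE)$values)))
  }
  if (max_re >= -1e-3) return(1e9 * (1 + max(max_re, 0)))
  ll <- 0
  for (r in seq_along(Ylist)) {
    ss <- dcm_state_space(params, spec, r, tr,
                          innovation_half_life = innovation_half_life)
    lr <- kalman_loglik_cpp(Ylist[[r]], ss$Phi, ss$Q, ss$C, ss$R, ss$m0,
                            ss$P0)
    if (!is.finite(lr)) return(1e10)
    ll <- ll + lr
  }
  lp <- sum(stats::dnorm(theta, tmpl$mean, tmpl$sd, log = TRUE))
  v <- -(ll + lp)
  if (!is.finite(v)) 1e10 else v
}

# central-difference Hessian of fn at x
numeric_hessian <- function(fn, x, h = NULL) {
  d <- length(x)
  if (is.null(h)) h <- 1e-3 * (1 + abs(x))
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h[i]
    fpp <- fn(x + ei); fmm <- fn(x - ei)
    H[i, i] <- (fpp - 2 * f0 + fmm) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- numeric(d); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  0.5 * (H + t(H))
}

#' Fit one DCM to the four rest runs of a subject
#'
#' Maximum-a-posteriori estimation of the free parameters (between-region
#' couplings, bilinear change parameters, log noise SDs) of the linearized
#' state-space model, followed by a Laplace approximation to the log model
#' evidence:
#' `log p(y|m) ~ log p(y|theta*) + log p(theta*) + (d/2) log 2pi - log|H|/2`
#' with `H` the negative Hessian of the log joint at the optimum. Runs are
#' filtered (constant + 256-s DCT), evaluated independently and combined
#' under a single parameter vector; state is not carried across runs.
#'
#' Optimization starts at the prior mean (or `init`); if it fails to
#' converge, jittered restarts are attempted.
#'
#' @param rest Rest-BOLD tibble (`run`, `volume`, region columns).
#' @param spec A [dcm_spec()].
#' @param priors A [dcm_priors()].
#' @param tr Sampling interval (s).
#' @param cutoff Rest high-pass cut-off (s).
#' @param discard Initial volumes dropped per run.
#' @param regions Region columns (default: first two non-index columns).
#' @param a_self Fixed self-connection (Hz).
#' @param init Optional named starting vector (e.g. from a null-model fit).
#' @param n_restarts Jittered restarts tried if the first start fails.
#' @param compute_hessian Compute the Laplace evidence (default `TRUE`;
#'   skipping it leaves `log_evidence` as `NA` and is only useful for
#'   diagnostics).
#' @param engine `"cpp"` (default) evaluates the objective in compiled
#'   code; `"r"` uses the reference R implementation (identical up to
#'   floating-point noise, used for cross-checking).
#' @param innovation_half_life Correlation half-life (s) of the endogenous
#'   fluctuations assumed by the state-space model (see
#'   [dcm_state_space()]); default 2 s, matching the temporally smooth
#'   spontaneous activity the generator emulates. Set to 0 for a
#'   white-noise drive.
#' @return Object of class `dcm_fit`: `theta` (MAP), `params`
#'   ([dcm_params()] at the MAP), `log_evidence`, `log_joint`,
#'   `posterior_sd`, `spec`, `convergence` (list), `n_volumes`.
#' @export
fit_dcm <- function(rest, spec, priors = dcm_priors(), tr = 2.176,
                    cutoff = 256, discard = 5L, regions = NULL,
                    a_self = -0.5, init = NULL, n_restarts = 2L,
                    compute_hessian = TRUE, engine = c("cpp", "r"),
                    innovation_half_life = 2) {
  engine <- match.arg(engine)
  lambda <- if (is.null(innovation_half_life) || innovation_half_life <= 0) {
    0
  } else {
    log(2) / innovation_half_life
  }
  if (is.null(regions)) {
    regions <- setdiff(names(rest), c("run", "volume", "subject"))[1:2]
  }
  Ylist <- prepare_rest_runs(rest, regions, tr, cutoff, discard)
  if (length(Ylist) != 4L) {
    abort_restdcm("expected exactly four rest runs", "restdcm_parameter_error")
  }
  hemo <- hemo_params()
  tmpl <- theta_template(spec, priors)
  fn <- if (engine == "cpp") {
    lin <- hemo_linear_approx(hemo)
    wts <- if (length(spec$modulators) > 0) {
      do.call(rbind, spec$modulators)
    } else {
      matrix(numeric(0), nrow = 0L, ncol = 4L)
    }
    conn_fwd <- as.integer(spec$connections == "forward")
    function(th) {
      neg_log_joint_cpp(th, Ylist, wts, conn_fwd, a_self, lin$H, lin$b_in,
                        lin$c_out, tr, tmpl$mean, tmpl$sd, lambda)
    }
  } else {
    function(th) neg_log_joint(th, Ylist, spec, priors, tr, a_self,
                               hemo, tmpl,
                               innovation_half_life = innovation_half_life)
  }
  start <- tmpl$mean
  if (!is.null(init)) {
    common <- intersect(names(init), tmpl$names)
    start[common] <- init[common]
  }
  best <- NULL
  tries <- 0L
  repeat {
    opt <- tryCatch(
      optim(start, fn, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-9)),
      error = function(e) NULL
    )
    ok <- !is.null(opt) && is.finite(opt$value) && opt$value < 1e8
    if (ok && (is.null(best) || opt$value < best$value)) best <- opt
    tries <- tries + 1L
    if (!is.null(best) && best$convergence == 0) break
    if (tries > n_restarts) break
    jit_sd <- pmax(tmpl$sd / 4, 1e-3)
    start <- tmpl$mean + rnorm(length(tmpl$mean), 0, jit_sd)
    names(start) <- tmpl$names
  }
  if (is.null(best)) {
    abort_restdcm("DCM fit failed to converge from any start",
                  "restdcm_convergence_error")
  }
  theta <- setNames(best$par, tmpl$names)
  d <- length(theta)
  log_joint <- -best$value
  log_ev <- NA_real_
  post_sd <- rep(NA_real_, d)
  hessian_pd <- NA
  if (compute_hessian) {
    H <- numeric_hessian(fn, theta)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    hessian_pd <- !is.null(ch)
    if (hessian_pd) {
      logdetH <- 2 * sum(log(diag(ch)))
      Hinv <- chol2inv(ch)
    } else {
      # nearest-PD fallback: clamp the spectrum (relative floor); the
      # evidence is flagged unreliable via hessian_pd = FALSE
      ee <- eigen(H, symmetric = TRUE)
      lam <- pmax(ee$values, max(abs(ee$values), 1) * 1e-10)
      logdetH <- sum(log(lam))
      Hinv <- ee$vectors %*% (t(ee$vectors) / lam)
    }
    log_ev <- log_joint + (d / 2) * log(2 * pi) - 0.5 * logdetH
    post_sd <- sqrt(pmax(diag(Hinv), 0))
  }
  structure(
    list(
      theta = theta,
      params = theta_to_params(theta, spec, a_self, hemo),
      log_evidence = log_ev,
      log_joint = log_joint,
      posterior_sd = setNames(post_sd, tmpl$names),
      spec = spec,
      priors = priors,
      regions = regions,
      n_volumes = sum(vapply(Ylist, nrow, 1L)),
      convergence = list(code = best$convergence, tries = tries,
                         hessian_pd = hessian_pd,
                         counts = unname(best$counts[1]))
    ),
    class = "dcm_fit"
  )
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("<dcm_fit> model:", x$spec$name, "\n")
  cat(sprintf("  log evidence %.2f (log joint %.2f), %d retained volumes\n",
              x$log_evidence, x$log_joint, x$n_volumes))
  cat(sprintf("  a_forward %.3f, a_backward %.3f Hz\n",
              x$theta[["a_forward"]], x$theta[["a_backward"]]))
  invisible(x)
}

#' Fit the whole model space to one subject
#'
#' Fits the null model first and warm-starts every other model from its
#' estimated couplings and noise levels (bilinear parameters start at the
#' prior mean).
#'
#' @param rest Rest-BOLD tibble.
#' @param models Named list of [dcm_spec()]s (default
#'   [build_model_space()]).
#' @param ... Passed to [fit_dcm()].
#' @return List with `fits` (named list of `dcm_fit`) and `log_ev`
#'   (tibble: model, log_evidence).
#' @export
fit_model_space <- function(rest, models = build_model_space(), ...) {
  fits <- vector("list", length(models))
  names(fits) <- names(models)
  init <- NULL
  if ("null" %in% names(models)) {
    fits[["null"]] <- fit_dcm(rest, models[["null"]], ...)
    init <- fits[["null"]]$theta
  }
  for (nm in setdiff(names(models), "null")) {
    fits[[nm]] <- fit_dcm(rest, models[[nm]], init = init, ...)
  }
  list(
    fits = fits,
    log_ev = tibble(
      model = names(fits),
      log_evidence = vapply(fits, function(f) f$log_evidence, 1.0)
    )
  )
}

#' Run-wise coupling change under a fitted model
#'
#' Multiplies the estimated bilinear parameters with the run-specific
#' modulator weights: `change_c(r) = sum_j m_j(r) b[j, c]`, reported
#' relative to the first run (whose value is zero under all shipped weight
#' patterns).
#'
#' @param fit A `dcm_fit` (or a [dcm_params()] with a matching `spec`
#'   passed explicitly).
#' @param spec The model specification (defaults to `fit$spec`).
#' @return Tibble with `connection`, `run` (1..4), `change` (Hz).
#' @export
#' @examples
#' sp <- build_model_space()[["C-fwd"]]
#' b <- matrix(c(0.2, 0.4), 2, 1,
#'             dimnames = list(c("adaptation", "consolidation"), "forward"))
#' coupling_timecourse(dcm_params(b = b), spec = sp)
coupling_timecourse <- function(fit, spec = NULL) {
  if (inherits(fit, "dcm_fit")) {
    params <- fit$params
    if (is.null(spec)) spec <- fit$spec
  } else {
    params <- fit
    if (is.null(spec)) {
      abort_restdcm("`spec` is required when passing raw parameters",
                    "restdcm_parameter_error")
    }
  }
  cons <- spec$connections
  if (length(cons) == 0) {
    return(tibble(connection = rep(c("forward", "backward"), each = 4L),
                  run = rep(1:4, 2L), change = 0))
  }
  out <- purrr::map(cons, function(con) {
    ch <- vapply(1:4, function(r) {
      sum(vapply(seq_along(spec$modulators), function(j) {
        spec$modulators[[j]][r] * params$b[j, con]
      }, 1.0))
    }, 1.0)
    tibble(connection = con, run = 1:4, change = ch - ch[1])
  })
  dplyr::bind_rows(out)
}
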