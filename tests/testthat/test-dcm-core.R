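# bilinear neuronal model, balloon hemodynamics, state space, Kalman
# likelihood, Laplace fitting

test_that("effective matrix applies the run weights to the right entries", {
  ms <- build_model_space()
  p0 <- dcm_params(a_forward = 0.1, a_backward = 0.2)
  # null model: the same A for every run
  for (r in 1:4) {
    expect_equal(effective_matrix(p0, ms[["null"]], r),
                 matrix(c(-0.5, 0.1, 0.2, -0.5), 2))
  }
  # adaptation on the forward connection: run 1 weight 0, run 2 weight 1
  bA <- matrix(0.15, 1, 1, dimnames = list("adaptation", "forward"))
  pA <- dcm_params(a_forward = 0.1, a_backward = 0.2, b = bA)
  expect_equal(effective_matrix(pA, ms[["A-fwd"]], 1),
               effective_matrix(p0, ms[["null"]], 1))
  expect_equal(effective_matrix(pA, ms[["A-fwd"]], 2)[2, 1], 0.1 + 0.15)
  # consolidation weight 2 in run 2: b = 0.1 contributes 0.2
  bC <- matrix(c(0, 0.1), 2, 1,
               dimnames = list(c("adaptation", "consolidation"), "forward"))
  pC <- dcm_params(a_forward = 0.1, a_backward = 0.2, b = bC)
  expect_equal(effective_matrix(pC, ms[["C-fwd"]], 2)[2, 1] -
                 effective_matrix(pC, ms[["C-fwd"]], 1)[2, 1], 0.2)
})

test_that("unstable effective matrices raise a stability error", {
  p <- dcm_params(a_forward = 0.6, a_backward = 0.6)
  expect_error(effective_matrix(p, build_model_space()[["null"]], 1),
               class = "restdcm_stability_error")
})

test_that("an impulse drives a delayed BOLD response with an undershoot", {
  dt <- 0.01
  z <- numeric(3000)          # 30 s
  z[1:50] <- 1                # 0.5 s neuronal burst
  y <- balloon_response_r(z, dt)
  peak_t <- (which.max(y) - 1) * dt
  expect_gte(peak_t, 4); expect_lte(peak_t, 8)
  expect_lt(min(y[(15 / dt):(30 / dt)]), 0)  # post-stimulus undershoot
})

test_that("the linearized hemodynamics match the balloon at small signals", {
  dt <- 0.01
  z <- numeric(4000)
  z[1:100] <- 0.01            # small 1-s input
  y_nl <- balloon_response_r(z, dt)
  y_lin <- linear_response_r(z, dt)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(y_nl - y_lin) / rms(y_nl), 0.05)
  # linearity: doubling the input doubles the linear response exactly
  y_lin2 <- linear_response_r(2 * z, dt)
  expect_equal(y_lin2, 2 * y_lin, tolerance = 1e-12)
  # DC gain is finite and positive
  expect_gt(hemo_linear_approx(hemo_params())$dc_gain, 0)
})

test_that("integration self-converges: halving dt changes the output < 1% RMS", {
  # deterministic comparison: a single scaled innovation produces the same
  # neuronal impulse on both grids (kick = sigma_z * sqrt(dt) * eps)
  A <- matrix(c(-0.5, 0.2, 0.1, -0.5), 2)
  hemo <- hemo_params()
  hv <- c(hemo$kappa, hemo$gamma, hemo$tau, hemo$alpha, hemo$E0, hemo$V0)
  run_impulse <- function(dt) {
    n <- round(40 / dt)
    eps <- matrix(0, n, 2)
    eps[1, 1] <- 0.5 / sqrt(dt)   # kick of 0.5 * sigma_z on region 1
    restdcm:::balloon_simulate_cpp(A, eps, 1.0, 0, dt, 1.0, 35L, 0L, hv)
  }
  y1 <- run_impulse(0.05)   # the default integration step
  y2 <- run_impulse(0.025)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(y1 - y2) / rms(y2), 0.01)
})

test_that("Kalman log-likelihood equals the brute-force joint density", {
  set.seed(101)
  for (i in 1:20) {
    inst <- random_ss_instance()
    ll_k <- loglik_kalman(inst$Y, inst)
    ll_b <- brute_force_loglik(inst$Y, inst$Phi, inst$Q, inst$C, inst$R,
                               inst$m0, inst$P0)
    expect_lt(abs(ll_k - ll_b), 1e-8)
  }
})

test_that("degenerate state variance reduces to the iid normal density", {
  set.seed(5)
  y <- matrix(rnorm(30, 0, 0.7), ncol = 1)
  ss <- list(Phi = matrix(0.9), Q = matrix(0), C = matrix(1),
             R = matrix(0.49), m0 = 0, P0 = matrix(0))
  expect_equal(loglik_kalman(y, ss),
               sum(stats::dnorm(y, 0, 0.7, log = TRUE)), tolerance = 1e-10)
  # doubling the observation SD on an all-zero series costs log(2) per
  # sample in negative log-likelihood
  y0 <- matrix(0, 50, 1)
  ss2 <- ss; ss2$R <- matrix(4 * 0.49)
  expect_equal((loglik_kalman(y0, ss) - loglik_kalman(y0, ss2)) / 50,
               log(2), tolerance = 1e-10)
})

test_that("the discretized DCM state space is consistent", {
  p <- dcm_params(a_forward = 0.2, a_backward = 0.1, sigma_z = 0.05,
                  sigma_obs = 0.1)
  ss <- dcm_state_space(p, build_model_space()[["null"]], run = 1)
  expect_lt(max(Mod(eigen(ss$Phi, only.values = TRUE)$values)), 1)
  # P0 is the stationary covariance: P = Phi P Phi' + Q
  expect_equal(ss$P0, ss$Phi %*% ss$P0 %*% t(ss$Phi) + ss$Q,
               tolerance = 1e-8)
  expect_true(all(eigen(ss$Q, only.values = TRUE)$values > -1e-10))
})

test_that("log joint is invariant under relabeling the two regions", {
  truth <- ground_truth()
  y <- gen_rest_bold(truth, quick_scan(50), seed = 42)
  ms <- build_model_space()
  pr <- dcm_priors()
  tr <- 2.176
  Y1 <- restdcm:::prepare_rest_runs(y, c("hippocampus", "striatum"), tr)
  Y2 <- restdcm:::prepare_rest_runs(y, c("striatum", "hippocampus"), tr)
  spec_f <- ms[["C-fwd"]]; spec_b <- ms[["C-bwd"]]
  tmpl_f <- restdcm:::theta_template(spec_f, pr)
  tmpl_b <- restdcm:::theta_template(spec_b, pr)
  hemo <- hemo_params()
  set.seed(9)
  for (i in 1:5) {
    th_f <- tmpl_f$mean + rnorm(length(tmpl_f$mean), 0, tmpl_f$sd / 4)
    # mirrored parameters: swap couplings, rename the modulated connection,
    # swap the per-region observation noises
    th_b <- th_f
    names(th_b) <- tmpl_f$names
    th_b[c("a_forward", "a_backward")] <- th_f[c(2, 1)]
    th_b[c("log_sigma_obs_1", "log_sigma_obs_2")] <-
      th_f[c("log_sigma_obs_2", "log_sigma_obs_1")]
    th_b <- setNames(th_b[c("a_forward", "a_backward",
                            "b_adaptation_forward",
                            "b_consolidation_forward",
                            "log_sigma_z", "log_sigma_obs_1",
                            "log_sigma_obs_2")], tmpl_b$names)
    v1 <- restdcm:::neg_log_joint(setNames(th_f, tmpl_f$names), Y1, spec_f,
                                  pr, tr, -0.5, hemo, tmpl_f)
    v2 <- restdcm:::neg_log_joint(th_b, Y2, spec_b, pr, tr, -0.5, hemo,
                                  tmpl_b)
    expect_lt(abs(v1 - v2), 1e-6)
  }
})

test_that("null-model couplings are recovered from low-noise data", {
  truth <- ground_truth(a_forward = 0.25, a_backward = 0.1,
                        spec = build_model_space()[["null"]], b = NULL,
                        obs_noise_sd = 0.02, drift_sd = 0.1)
  y <- gen_rest_bold(truth, quick_scan(140), seed = 8)
  fit <- fit_dcm(y, build_model_space()[["null"]])
  expect_lt(abs(fit$theta[["a_forward"]] - 0.25), 0.08)
  expect_lt(abs(fit$theta[["a_backward"]] - 0.1), 0.08)
  expect_true(fit$convergence$code == 0)
  expect_true(is.finite(fit$log_evidence))
  # posterior SDs are on a sane scale for this design
  expect_true(all(fit$posterior_sd[c("a_forward", "a_backward")] < 0.2))
})

test_that("a richer nested model attains at least the null's log joint", {
  truth <- ground_truth()
  y <- gen_rest_bold(truth, quick_scan(60), seed = 13)
  ms <- build_model_space()
  f0 <- fit_dcm(y, ms[["null"]])
  f1 <- fit_dcm(y, ms[["L-both"]], init = f0$theta)
  # the learning model nests the null at b = 0 (identical prior density at
  # the shared optimum is not guaranteed, so compare the data fit)
  expect_gte(f1$log_joint, f0$log_joint - 3.5)
})

test_that("coupling time-course multiplies weights into run-wise changes", {
  sp <- build_model_space()[["C-fwd"]]
  b <- matrix(c(0.2, 0.4), 2, 1,
              dimnames = list(c("adaptation", "consolidation"), "forward"))
  tc <- coupling_timecourse(dcm_params(b = b), spec = sp)
  expect_equal(tc$change, c(0, 1.0, 0.4, 0.6))

  # null model: all zero
  tc0 <- coupling_timecourse(dcm_params(), spec = build_model_space()[["null"]])
  expect_true(all(tc0$change == 0))

  # the consolidation profile peaks at run 2 with equal persistence at
  # runs 3-4, for any positive parameters
  set.seed(2)
  for (i in 1:20) {
    bb <- matrix(runif(2, 0.01, 0.5), 2, 1,
                 dimnames = list(c("adaptation", "consolidation"), "forward"))
    tc_i <- coupling_timecourse(
      dcm_params(a_forward = 0, a_backward = 0, b = bb), spec = sp
    )
    expect_equal(which.max(tc_i$change), 2L)
    expect_gt(tc_i$change[3], 0)
    expect_equal(tc_i$change[4] - tc_i$change[3], bb["adaptation", 1])
  }
})
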