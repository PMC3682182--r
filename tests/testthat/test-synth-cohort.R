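# synthetic cohort generators: behavior, rest/task BOLD, cohort on disk

test_that("behavior generator emits the exact session structure", {
  tt <- gen_behavior(task_design(), ground_truth(), seed = 3)
  expect_equal(nrow(tt), 800L)
  expect_equal(sum(tt$condition == "motion"), 400L)
  expect_equal(sum(tt$condition == "control"), 400L)
  expect_equal(dplyr::n_distinct(tt$block[tt$condition == "motion"]), 25L)
  counts <- dplyr::count(tt, condition, block)
  expect_true(all(counts$n == 16L))
  expect_true(all(is.na(tt$rt_s) | tt$rt_s > 0))
  # control accuracy near ceiling
  expect_gte(mean(tt$correct[tt$condition == "control"]), 0.95)
})

test_that("behavior generation is deterministic in the seed", {
  a <- gen_behavior(task_design(), ground_truth(), seed = 9)
  b <- gen_behavior(task_design(), ground_truth(), seed = 9)
  expect_identical(a, b)
})

test_that("zero learning rate produces a trendless IE series", {
  truth <- ground_truth(behavior = list(learning_rate = 0))
  tt <- gen_behavior(task_design(), truth, seed = 21)
  ie <- block_inverse_efficiency(exclude_rt_outliers(tt))
  sl <- summary(stats::lm(ie ~ block, data = ie))$coefficients["block", ]
  expect_gt(sl["Pr(>|t|)"], 0.01)
})

test_that("with rt_sd = 0 and perfect accuracy, IE equals the mean RT", {
  truth <- ground_truth(behavior = list(rt_sd = 0, acc_start = 1,
                                        acc_asymptote = 1, miss_rate = 0))
  tt <- gen_behavior(task_design(), truth, seed = 2)
  ie <- block_inverse_efficiency(tt)
  expect_equal(ie$ie, ie$mean_rt)
  expect_true(all(ie$accuracy == 1))
})

test_that("invalid behavioral parameters are rejected", {
  expect_error(ground_truth(behavior = list(learning_rate = -0.1)),
               class = "restdcm_parameter_error")
  expect_error(ground_truth(behavior = list(control_rt_mean = 0)),
               class = "restdcm_parameter_error")
})

test_that("rest generator emits four labeled runs of the configured length", {
  sc <- quick_scan(40)
  y <- gen_rest_bold(ground_truth(), sc, seed = 1)
  expect_equal(sort(unique(y$run)), 1:4)
  expect_true(all(dplyr::count(y, run)$n == 40L))
  expect_named(y, c("run", "volume", "hippocampus", "striatum"))
  expect_identical(y, gen_rest_bold(ground_truth(), sc, seed = 1))
})

test_that("unstable effective coupling is refused naming the run", {
  b <- matrix(c(0.05, 0.05, 0.3, 0.3), 2, byrow = TRUE,
              dimnames = list(c("adaptation", "consolidation"),
                              c("forward", "backward")))
  expect_error(ground_truth(b = b), class = "restdcm_stability_error")
})

test_that("no-change truth yields statistically exchangeable runs", {
  truth <- ground_truth(spec = build_model_space()[["null"]], b = NULL)
  sc <- quick_scan(90)
  inter <- vapply(1:8, function(s) {
    y <- gen_rest_bold(truth, sc, seed = 300 + s)
    sl <- run_coupling_slope(y, "hippocampus", "striatum", cutoff = 256)
    factorial_contrasts(sl)$interaction
  }, 1.0)
  expect_gt(stats::t.test(inter)$p.value, 0.01)
})

test_that("consolidation truth raises the run-2 coupling most", {
  # long simulation: lagged cross-covariance between regions is largest in
  # run 2, with runs 3-4 intermediate between runs 1 and 2
  truth <- ground_truth(obs_noise_sd = 0.02, drift_sd = 0)
  y <- gen_rest_bold(truth, quick_scan(500), seed = 77)
  ccov <- vapply(1:4, function(r) {
    d <- y[y$run == r, ]
    h <- scale(d$hippocampus, scale = FALSE)
    s <- scale(d$striatum, scale = FALSE)
    n <- length(h)
    mean(h[-1] * s[-n] + h[-n] * s[-1]) / 2
  }, 1.0)
  expect_gt(ccov[2], ccov[1])
  expect_gt(ccov[2], ccov[3])
  expect_gt(ccov[2], ccov[4])
  expect_gt(min(ccov[3], ccov[4]), ccov[1])
})

test_that("the simulated neuronal process is stationary within a run", {
  truth <- ground_truth(spec = build_model_space()[["null"]], b = NULL,
                        drift_sd = 0)
  diffs <- vapply(1:20, function(s) {
    y <- gen_rest_bold(truth, quick_scan(120), seed = 900 + s)
    d <- y$hippocampus[y$run == 1]
    stats::var(d[1:60]) - stats::var(d[61:120])
  }, 1.0)
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("zero endogenous noise keeps the BOLD at the hemodynamic fixed point", {
  truth <- ground_truth(sigma_z = 0, obs_noise_sd = 0, drift_sd = 0)
  y <- gen_rest_bold(truth, quick_scan(20), seed = 1)
  expect_lt(max(abs(y$hippocampus)), 1e-10)
  expect_lt(max(abs(y$striatum)), 1e-10)
})

test_that("task generator emits five runs and encodes the IE modulation", {
  sc <- scan_config()
  truth <- ground_truth(task = list(noise_sd = 0, drift_sd = 0))
  y <- gen_task_bold(task_design(), truth, sc, seed = 1)
  expect_equal(sort(unique(y$run)), 1:5)
  expect_true(all(dplyr::count(y, run)$n == 246L))

  # noiseless recovery of the modulation gain by the first-level GLM
  onsets <- task_block_onsets(task_design(), sc)
  bh <- truth$behavior
  ie_fit <- bh$ie_asymptote + bh$ie_amplitude * exp(-bh$learning_rate * (1:25))
  X <- build_design_matrix(onsets, ie_fit, sc)
  yv <- y[order(y$run, y$volume), ][["hippocampus"]][attr(X, "keep_rows")]
  fit <- fit_first_level(yv, X)
  est <- fit$contrasts$estimate[fit$contrasts$contrast == "ie"]
  expect_lt(abs(est - truth$task$ie_gain) / truth$task$ie_gain, 0.01)
  expect_lt(abs(fit$betas[["motion"]] - truth$task$motion_amp), 0.01)
})

test_that("zero modulation gain gives a near-zero IE beta", {
  sc <- scan_config()
  truth <- ground_truth(task = list(ie_gain = 0))
  onsets <- task_block_onsets(task_design(), sc)
  bh <- truth$behavior
  ie_fit <- bh$ie_asymptote + bh$ie_amplitude * exp(-bh$learning_rate * (1:25))
  X <- build_design_matrix(onsets, ie_fit, sc)
  ts <- vapply(1:5, function(s) {
    y <- gen_task_bold(task_design(), truth, sc, seed = 40 + s)
    yv <- y[order(y$run, y$volume), ][["hippocampus"]][attr(X, "keep_rows")]
    fit <- fit_first_level(yv, X)
    fit$contrasts$t[fit$contrasts$contrast == "ie"]
  }, 1.0)
  expect_gt(stats::t.test(ts)$p.value, 0.01)
})

test_that("ground-truth sidecar round-trips losslessly", {
  tmp <- tempfile(fileext = ".json")
  truth <- ground_truth()
  write_ground_truth(truth, tmp)
  back <- read_ground_truth(tmp)
  expect_equal(back, truth, tolerance = 0)
  # the sidecar echoes the consolidation run-weight rows
  j <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(as.numeric(j$model$modulators$adaptation), c(0, 1, 0, 1))
  expect_equal(as.numeric(j$model$modulators$consolidation), c(0, 2, 1, 1))
})

test_that("cohort writer is deterministic, validated, and refuses overwrites", {
  sc <- quick_scan(20)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- gen_cohort(2, d1, master_seed = 5, scan = sc)
  m2 <- gen_cohort(2, d2, master_seed = 5, scan = sc)
  for (f in c("behavior.tsv", "rest_bold.tsv", "task_bold.tsv",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, "sub-01", f)),
                     readLines(file.path(d2, "sub-01", f)))
  }
  expect_equal(nrow(m1), 2L)
  expect_error(gen_cohort(2, d1, master_seed = 5, scan = sc),
               class = "restdcm_io_error")
  expect_error(gen_cohort(0, tempfile()), class = "restdcm_parameter_error")
  unlink(c(d1, d2), recursive = TRUE)
})
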