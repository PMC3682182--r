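# HRF, DCT filtering and the first-level / group GLM

test_that("HRF kernel is unit-sum, peaks at 5-6 s, and preserves constants", {
  k <- hrf_kernel(0.1)
  expect_equal(sum(k), 1)
  peak_t <- (which.max(k) - 1) * 0.1
  expect_gte(peak_t, 5); expect_lte(peak_t, 6)
  # late undershoot is negative
  expect_lt(min(k[(15 / 0.1):(25 / 0.1)]), 0)
  # LTI identity: once the kernel fully overlaps, a constant stays constant
  x <- rep(2, 400)
  y <- stats::convolve(x, rev(k), type = "open")[seq_along(x)]
  expect_equal(y[321:400], rep(2, 80), tolerance = 1e-10)
})

test_that("DCT basis has the documented column count and is orthonormal", {
  X <- dct_highpass_basis(276, 2.176, 256)
  expect_equal(ncol(X), 4L)  # floor(2 * 276 * 2.176 / 256) = floor(4.69)
  expect_equal(crossprod(X), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # each column is orthogonal to the constant
  expect_lt(max(abs(colSums(X))), 1e-10)
  expect_equal(ncol(dct_highpass_basis(246, 2.176, 128)), 8L)
  expect_error(dct_highpass_basis(100, 2.176, 4),
               class = "restdcm_parameter_error")
})

test_that("256-s DCT filtering removes a 300-s-period sinusoid", {
  n <- 276; tr <- 2.176
  # 300-s-period cosine sampled at the volume midpoints (the phase
  # convention of the DCT boundary conditions)
  y <- cos(2 * pi * ((0:(n - 1)) + 0.5) * tr / 300)
  Z <- cbind(1, dct_highpass_basis(n, tr, 256))
  res <- y - Z %*% qr.coef(qr(Z), y)
  expect_lt(sum(res^2) / sum((y - mean(y))^2), 0.05)
})

test_that("first-level OLS is exact on noiseless data and flags rank loss", {
  set.seed(1)
  X <- cbind(motion = rnorm(50), control = rnorm(50), const = 1)
  beta <- c(2, -1, 0.5)
  y <- X %*% beta
  fit <- fit_first_level(y, X, contrasts = list(m = c(motion = 1)))
  expect_equal(unname(fit$betas), beta, tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)
  expect_equal(fit$df, 47L)

  Xbad <- cbind(X, dup = X[, "motion"])
  err <- tryCatch(fit_first_level(y, Xbad), error = function(e) e)
  expect_s3_class(err, "restdcm_rank_error")
  expect_match(conditionMessage(err), "dup|motion")
})

test_that("contrast t is invariant to regressor rescaling", {
  set.seed(2)
  X <- cbind(motion = rnorm(60), const = 1)
  y <- 0.5 * X[, 1] + rnorm(60)
  t1 <- fit_first_level(y, X, list(m = c(motion = 1)))$contrasts$t
  X2 <- X; X2[, 1] <- X2[, 1] * 10
  t2 <- fit_first_level(y, X2, list(m = c(motion = 1)))$contrasts$t
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("IE-modulator t has the nominal type-I error under pure noise", {
  sc <- scan_config(task_volumes = 80L, n_task_runs = 2L)
  design <- task_design(n_blocks_per_condition = 4L, trials_per_block = 8L)
  onsets <- task_block_onsets(design, sc, gap_s = 10)
  X <- build_design_matrix(onsets, seq(1.2, 0.8, length.out = 4), sc)
  set.seed(33)
  n_sim <- 400
  crit <- stats::qt(0.975, df = nrow(X) - ncol(X))
  rej <- replicate(n_sim, {
    y <- rnorm(nrow(X))
    fit <- fit_first_level(y, X)
    abs(fit$contrasts$t[fit$contrasts$contrast == "ie"]) > crit
  })
  # binomial 99% band around 0.05 for 400 draws
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("group t-test behaves and flags degenerate input", {
  res <- group_ttest(c(1, 2, 3, 2, 1.5))
  expect_equal(res$df, 4)
  expect_gt(res$t, 0)
  # symmetric values around zero give t = 0
  expect_equal(group_ttest(c(-2, 2, -1, 1))$t, 0)
  expect_error(group_ttest(rep(3, 5)), class = "restdcm_degenerate_error")
  expect_error(group_ttest(1), class = "restdcm_parameter_error")
})

test_that("positive learning modulation yields a positive group effect", {
  sc <- scan_config()
  design <- task_design()
  truth <- ground_truth()
  onsets <- task_block_onsets(design, sc)
  bh <- truth$behavior
  ie_fit <- bh$ie_asymptote + bh$ie_amplitude * exp(-bh$learning_rate * (1:25))
  X <- build_design_matrix(onsets, ie_fit, sc)
  betas <- vapply(1:6, function(s) {
    y <- gen_task_bold(design, truth, sc, seed = 600 + s)
    yv <- y[order(y$run, y$volume), ][["hippocampus"]][attr(X, "keep_rows")]
    fit <- fit_first_level(yv, X)
    fit$contrasts$estimate[fit$contrasts$contrast == "ie"]
  }, 1.0)
  res <- group_ttest(betas)
  expect_gt(res$t, 0)
  expect_lt(res$p, 0.05)
})
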