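# inverse efficiency, outlier exclusion and learning-curve fitting

test_that("RT outlier exclusion removes exactly the trials beyond 3 SD", {
  # 15 trials at 0.5 s and one at 1.0 s: mean 0.53125, sd 0.125,
  # so the 1.0 s trial deviates by 3.75 SD and everything else by 0.25 SD
  tt <- tibble::tibble(condition = "motion", block = 1L,
                       rt_s = c(rep(0.5, 15), 1.0), correct = 1L)
  out <- exclude_rt_outliers(tt)
  expect_equal(nrow(out), 15L)
  expect_equal(n_excluded(out), 1L)
  expect_false(1.0 %in% out$rt_s)

  # a visually extreme trial can still be within 3 SD when it inflates the
  # block SD itself: [0.5 0.5 0.5 5.0] has mean 1.625, sd 2.25 -> 1.5 SD
  tt2 <- tibble::tibble(condition = "motion", block = 1L,
                        rt_s = c(0.5, 0.5, 0.5, 5.0), correct = 1L)
  expect_equal(nrow(exclude_rt_outliers(tt2)), 4L)

  # identical RTs: zero SD, nothing deviates, nothing removed
  tt3 <- tibble::tibble(condition = "motion", block = 1L,
                        rt_s = rep(0.7, 8), correct = 1L)
  expect_equal(nrow(exclude_rt_outliers(tt3)), 8L)
})

test_that("outlier exclusion is a single pass and idempotent on one-outlier blocks", {
  tt <- tibble::tibble(condition = "motion", block = 1L,
                       rt_s = c(rep(0.5, 15), 1.0), correct = 1L)
  once <- exclude_rt_outliers(tt)
  twice <- exclude_rt_outliers(once)
  expect_equal(twice$rt_s, once$rt_s)
})

test_that("outlier exclusion validates its input", {
  expect_error(
    exclude_rt_outliers(tibble::tibble(condition = "motion", block = 1L,
                                       rt_s = 0.5, correct = 1L)),
    class = "restdcm_parameter_error"
  )
})

test_that("block inverse efficiency is mean RT over accuracy", {
  # accuracy 1: IE equals the mean RT
  tt <- tibble::tibble(condition = "motion", block = 1L,
                       rt_s = c(0.7, 0.9), correct = 1L)
  expect_equal(block_inverse_efficiency(tt)$ie, 0.8)

  # mean RT 0.6, accuracy 0.75 -> IE 0.8
  tt2 <- tibble::tibble(condition = "motion", block = 1L,
                        rt_s = rep(0.6, 4), correct = c(1L, 1L, 1L, 0L))
  expect_equal(block_inverse_efficiency(tt2)$ie, 0.8)

  # omitted responses count as errors but contribute no RT
  tt3 <- tibble::tibble(condition = "motion", block = 1L,
                        rt_s = c(0.6, 0.6, NA), correct = c(1L, 1L, 0L))
  expect_equal(block_inverse_efficiency(tt3)$ie, 0.6 / (2 / 3))

  # zero-accuracy block is flagged, not silently dropped
  tt4 <- tibble::tibble(condition = "motion", block = 1L,
                        rt_s = c(0.6, 0.7), correct = 0L)
  expect_error(block_inverse_efficiency(tt4),
               class = "restdcm_degenerate_error")
})

test_that("IE is computed per block, ordered, and invariant to trial order", {
  tt <- gen_behavior(task_design(), ground_truth(), seed = 5)
  ie <- block_inverse_efficiency(exclude_rt_outliers(tt))
  expect_equal(nrow(ie), 25L)
  expect_equal(ie$block, 1:25)
  set.seed(1)
  ie2 <- block_inverse_efficiency(
    exclude_rt_outliers(tt[sample(nrow(tt)), ])
  )
  expect_equal(ie2$ie, ie$ie)
})

test_that("exponential fit recovers noiseless parameters to 1e-6", {
  x <- 1:25
  y <- 2.0 * exp(-0.1 * x)
  fit <- fit_learning_curve(y)
  expect_lt(abs(fit$a - 2.0), 1e-6)
  expect_lt(abs(fit$b - 0.1), 1e-6)
  expect_equal(fit$ie_fitted, y, tolerance = 1e-6)
})

test_that("flat and steep learning curves behave at the limits", {
  fit_const <- fit_learning_curve(rep(1.3, 25))
  expect_lt(abs(fit_const$b), 1e-6)
  expect_lt(abs(fit_const$a - 1.3), 1e-4)

  y_steep <- 1 * exp(-3 * (1:25)) + 1e-12
  fit_steep <- fit_learning_curve(y_steep)
  expect_lt(abs(fit_steep$b - 3), 1e-4)
  expect_true(all(fit_steep$ie_fitted[-(1:2)] < 0.01 * fit_steep$ie_fitted[1]))
})

test_that("exponential fit never loses to the best constant fit", {
  set.seed(42)
  for (i in 1:20) {
    y <- (0.6 + runif(1)) * exp(-runif(1, 0, 0.3) * (1:25)) + 0.5
    y <- y * exp(rnorm(25, 0, 0.1))
    fit <- fit_learning_curve(y)
    rss_const <- sum((y - mean(y))^2)
    expect_lte(fit$rss, rss_const * (1 + 1e-8))
  }
})

test_that("learning rate is recovered under 10% multiplicative noise", {
  set.seed(7)
  rel_err <- replicate(200, {
    a <- runif(1, 0.8, 2); b <- runif(1, 0.05, 0.3)
    y <- a * exp(-b * (1:25)) * exp(rnorm(25, 0, 0.1))
    fit <- fit_learning_curve(y)
    abs(fit$b - b) / b
  })
  expect_lt(median(rel_err), 0.2)
})

test_that("fit input validation and negative-rate flag work", {
  expect_error(fit_learning_curve(c(1, 2)), class = "restdcm_parameter_error")
  expect_error(fit_learning_curve(c(1, -1, 2)),
               class = "restdcm_parameter_error")
  fit <- fit_learning_curve(0.5 * exp(0.05 * (1:25)))
  expect_true(fit$flagged_negative_rate)
  expect_lt(fit$b, 0)
})

test_that("tidy/glance/autoplot methods of the learning curve work", {
  fit <- fit_learning_curve(2 * exp(-0.1 * (1:25)))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  gl <- glance(fit)
  expect_equal(gl$n_blocks, 25L)
  expect_s3_class(autoplot(fit), "ggplot")
})
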