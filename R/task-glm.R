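#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak near 5--6 s, undershoot
#' peaking near 15 s, peak-to-undershoot ratio 6), sampled on a 32-s support
#' and normalized to unit sum, so that convolving a constant series leaves
#' its level unchanged.
#'
#' @param dt Sampling step (s).
#' @param length_s Kernel support (s).
#' @return Numeric vector of kernel weights summing to 1.
#' @export
#' @examples
#' k <- hrf_kernel(0.1)
#' sum(k)
hrf_kernel <- function(dt, length_s = 32) {
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  t <- seq(0, length_s, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Discrete-cosine high-pass filter basis
#'
#' Orthonormal DCT columns whose periods exceed the cut-off, i.e. the
#' `floor(2 * n_volumes * tr / cutoff)` slowest non-constant components.
#' Regressing these out of a series removes fluctuations slower than the
#' cut-off (scanner drift, between-run offsets) while leaving faster
#' fluctuations nearly untouched.
#'
#' @param n_volumes Number of time points.
#' @param tr Sampling interval (s).
#' @param cutoff High-pass cut-off period (s); must exceed `2 * tr`.
#' @return Matrix `n_volumes` x K of orthonormal columns (no constant).
#' @export
#' @examples
#' ncol(dct_highpass_basis(276, 2.176, 256)) # 4
dct_highpass_basis <- function(n_volumes, tr, cutoff) {
  n_volumes <- stopifnot_count(n_volumes, "n_volumes", min = 2L)
  stopifnot_scalar_number(tr, "tr", positive = TRUE)
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (cutoff <= 2 * tr) {
    abort_restdcm("`cutoff` must exceed twice the sampling interval",
                  "restdcm_parameter_error")
  }
  K <- floor(2 * n_volumes * tr / cutoff)
  t <- seq_len(n_volumes) - 1L
  if (K < 1L) {
    return(matrix(numeric(0), nrow = n_volumes, ncol = 0L))
  }
  X <- vapply(seq_len(K), function(k) {
    sqrt(2 / n_volumes) * cos(pi * (2 * t + 1) * k / (2 * n_volumes))
  }, numeric(n_volumes))
  colnames(X) <- paste0("dct_", seq_len(K))
  X
}

#' Block onsets of the task session
#'
#' Deterministic block timing: within every task run the blocks alternate
#' between conditions, each block lasting
#' `trials_per_block * (stimulus_duration + response_window)` seconds, with
#' a fixed lead-in and inter-block fixation gap.
#'
#' @param design A [task_design()].
#' @param scan A [scan_config()].
#' @param start_condition Condition of the first block of the session.
#' @param lead_in_s,gap_s Lead-in before the first block and gap between
#'   blocks (s).
#' @return Tibble with `run`, `block` (per-condition index), `condition`,
#'   `onset_s` (relative to run start), `duration_s`.
#' @export
task_block_onsets <- function(design, scan, start_condition = "motion",
                              lead_in_s = 12, gap_s = 20) {
  nb <- design$n_blocks_per_condition
  n_total <- 2L * nb
  per_run <- n_total / scan$n_task_runs
  if (per_run != round(per_run)) {
    abort_restdcm("blocks do not divide evenly over task runs",
                  "restdcm_parameter_error")
  }
  block_dur <- design$trials_per_block *
    (design$stimulus_duration + design$response_window)
  run_len <- scan$task_volumes * scan$tr
  if (lead_in_s + per_run * block_dur + (per_run - 1) * gap_s > run_len) {
    abort_restdcm("blocks do not fit into the task run", "restdcm_parameter_error")
  }
  other <- setdiff(design$conditions, start_condition)
  tibble(
    order = seq_len(n_total),
    run = ceiling(order / per_run),
    block = rep(seq_len(nb), each = 2L),
    condition = rep(c(start_condition, other), nb)
  ) %>%
    group_by(run) %>%
    mutate(onset_s = lead_in_s + (seq_len(dplyr::n()) - 1L) *
             (block_dur + gap_s),
           duration_s = block_dur) %>%
    ungroup() %>%
    select(run, block, condition, onset_s, duration_s)
}

# per-run convolved task regressors sampled at every volume (full run,
# nothing discarded). ie_centered: named by per-condition block index,
# already mean-centered. Returns n_volumes x 3 matrix.
task_regressors <- function(onsets_run, ie_centered, scan,
                            microtime = scan$tr / 16) {
  n_vol <- scan$task_volumes
  run_len <- n_vol * scan$tr
  t_grid <- seq(0, run_len, by = microtime)
  box <- function(rows, weight) {
    u <- numeric(length(t_grid))
    for (i in seq_len(nrow(rows))) {
      on <- rows$onset_s[i]
      w <- if (is.list(weight)) weight[[as.character(rows$block[i])]] else weight
      u[t_grid >= on & t_grid < on + rows$duration_s[i]] <- w
    }
    u
  }
  h <- hrf_kernel(microtime)
  conv_sample <- function(u) {
    v <- stats::convolve(u, rev(h), type = "open")[seq_along(u)]
    v[pmin(length(v), round((0:(n_vol - 1)) * scan$tr / microtime) + 1L)]
  }
  motion <- onsets_run[onsets_run$condition == "motion", ]
  control <- onsets_run[onsets_run$condition == "control", ]
  ie_w <- as.list(setNames(ie_centered, names(ie_centered)))
  cbind(
    motion = conv_sample(box(motion, 1)),
    control = conv_sample(box(control, 1)),
    motion_ie = conv_sample(box(motion, ie_w))
  )
}

#' Build the first-level design matrix
#'
#' Condition boxcars convolved with the canonical HRF, the IE-modulated
#' motion regressor (fitted inverse-efficiency values, mean-centered per
#' run before convolution weighting), per-run DCT high-pass columns and
#' per-run intercepts. The first `discard` volumes of every run are dropped.
#'
#' @param onsets Output of [task_block_onsets()].
#' @param ie_fitted Fitted per-block inverse efficiency, one value per
#'   motion block (length `n_blocks_per_condition`).
#' @param scan A [scan_config()].
#' @param cutoff High-pass cut-off (s) for the task data.
#' @param discard Initial volumes dropped per run.
#' @return Design matrix with named columns and attributes `keep_rows`
#'   (logical index into the concatenated full-length series) and
#'   `task_cols`.
#' @export
build_design_matrix <- function(onsets, ie_fitted, scan, cutoff = 128,
                                discard = scan$discard_initial) {
  runs <- sort(unique(onsets$run))
  n_vol <- scan$task_volumes
  Xs <- list(); keeps <- list()
  for (r in runs) {
    on_r <- onsets[onsets$run == r, ]
    blocks_r <- on_r$block[on_r$condition == "motion"]
    ie_r <- ie_fitted[blocks_r]
    ie_c <- setNames(ie_r - mean(ie_r), blocks_r)
    Xtask <- task_regressors(on_r, ie_c, scan)
    keep <- seq_len(n_vol) > discard
    dct <- dct_highpass_basis(sum(keep), scan$tr, cutoff)
    colnames(dct) <- paste0("run", r, "_", colnames(dct))
    Xr <- cbind(Xtask[keep, , drop = FALSE], dct,
                setNames(data.frame(rep(1, sum(keep))),
                         paste0("run", r, "_const")))
    Xs[[as.character(r)]] <- Xr
    keeps[[as.character(r)]] <- keep
  }
  # block-diagonal in the run-specific columns, stacked task columns
  task_cols <- c("motion", "control", "motion_ie")
  all_cols <- unique(unlist(lapply(Xs, colnames)))
  X <- matrix(0, nrow = sum(vapply(keeps, sum, 1L)), ncol = length(all_cols),
              dimnames = list(NULL, all_cols))
  at <- 0L
  for (r in names(Xs)) {
    nr <- nrow(Xs[[r]])
    X[at + seq_len(nr), colnames(Xs[[r]])] <- as.matrix(Xs[[r]])
    at <- at + nr
  }
  attr(X, "keep_rows") <- unlist(keeps, use.names = FALSE)
  attr(X, "task_cols") <- task_cols
  X
}

#' Ordinary least-squares first-level fit
#'
#' Fits `y = X beta + e` by OLS and evaluates the requested contrasts with
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^{-1} c)`; the residual degrees of
#' freedom are `n - rank(X)`, so filtering and nuisance columns included in
#' `X` are accounted for.
#'
#' @param y Numeric response vector (one ROI series, rows matching `X`).
#' @param X Design matrix with named columns (see [build_design_matrix()]).
#' @param contrasts Named list of contrast vectors; each either a full
#'   numeric vector over columns, or a named vector of weights on a subset
#'   of columns (e.g. `list(ie = c(motion_ie = 1))`).
#' @return Object of class `first_level_fit` with elements `betas` (named),
#'   `sigma2`, `df`, `contrasts` (tibble with estimate, se, t, p).
#' @export
fit_first_level <- function(y, X, contrasts = list(ie = c(motion_ie = 1))) {
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    abort_restdcm("`y` and `X` have different numbers of rows",
                  "restdcm_parameter_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort_restdcm(
      sprintf("design matrix is rank deficient; collinear columns: %s",
              paste(bad, collapse = ", ")),
      "restdcm_rank_error"
    )
  }
  beta <- qr.coef(qrX, y)
  res <- y - as.numeric(X %*% beta)
  df <- length(y) - qrX$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  rownames(XtXinv) <- colnames(XtXinv) <- colnames(X)
  ct <- purrr::imap(contrasts, function(cv, nm) {
    cfull <- numeric(ncol(X)); names(cfull) <- colnames(X)
    if (!is.null(names(cv))) {
      if (!all(names(cv) %in% colnames(X))) {
        abort_restdcm("contrast names a column absent from the design",
                      "restdcm_parameter_error")
      }
      cfull[names(cv)] <- cv
    } else {
      if (length(cv) != ncol(X)) {
        abort_restdcm("unnamed contrast must cover every column",
                      "restdcm_parameter_error")
      }
      cfull[] <- cv
    }
    est <- sum(cfull * beta)
    se <- sqrt(sigma2 * as.numeric(t(cfull) %*% XtXinv %*% cfull))
    tval <- est / se
    tibble(contrast = nm, estimate = est, se = se, t = tval, df = df,
           p = 2 * stats::pt(-abs(tval), df))
  })
  structure(
    list(betas = beta, sigma2 = sigma2, df = df,
         contrasts = dplyr::bind_rows(ct)),
    class = "first_level_fit"
  )
}

#' Group-level one-sample t-test
#'
#' Tests per-subject contrast values against zero (two-sided), the
#' second-level analogue of passing contrast images to a one-sample t-test.
#'
#' @param values Numeric vector, one value per subject.
#' @return Tibble with `estimate`, `t`, `df`, `p`, `n`.
#' @export
#' @examples
#' group_ttest(c(0.6, 0.8, 0.3, 0.9, 0.5))
group_ttest <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    abort_restdcm("need at least two subjects", "restdcm_parameter_error")
  }
  if (stats::sd(values) == 0) {
    abort_restdcm(
      "zero variance across subjects: t statistic is degenerate",
      "restdcm_degenerate_error"
    )
  }
  ht <- stats::t.test(values)
  tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value, n = length(values))
}
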