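#' Run-wise coupling slope between a seed and a target region
#'
#' For every rest run, the first `discard` volumes are dropped, a nuisance
#' basis (constant plus the 256-s DCT high-pass columns by default) is
#' partialled out of both series, and the OLS regression slope of the
#' target on the seed is returned. This is the elementary statistic of the
#' psychophysiological-interaction screen: a change of the slope across
#' runs indicates a change in coupling.
#'
#' @param rest Tibble of rest BOLD with columns `run`, `volume` and one
#'   column per region (see [gen_rest_bold()]).
#' @param seed_region,target_region Column names.
#' @param tr Sampling interval (s).
#' @param cutoff High-pass cut-off (s) for rest data.
#' @param discard Initial volumes dropped per run.
#' @return Tibble with `run` and `slope`.
#' @export
run_coupling_slope <- function(rest, seed_region, target_region,
                               tr = 2.176, cutoff = 256, discard = 5L) {
  for (nm in c("run", "volume", seed_region, target_region)) {
    if (!nm %in% names(rest)) {
      abort_restdcm(sprintf("column `%s` missing from rest data", nm),
                    "restdcm_parameter_error")
    }
  }
  runs <- sort(unique(rest$run))
  out <- purrr::map(runs, function(r) {
    d <- rest[rest$run == r, ]
    d <- d[order(d$volume), ]
    keep <- seq_len(nrow(d)) > discard
    s <- d[[seed_region]][keep]
    y <- d[[target_region]][keep]
    Z <- cbind(const = 1, dct_highpass_basis(length(s), tr, cutoff))
    resid_on <- function(v) v - Z %*% qr.coef(qr(Z), v)
    sr <- as.numeric(resid_on(s))
    yr <- as.numeric(resid_on(y))
    if (sum(sr^2) < 1e-12 * length(sr)) {
      abort_restdcm(
        sprintf("seed region has (near) zero variance after filtering in run %d", r),
        "restdcm_degenerate_error"
      )
    }
    tibble(run = r, slope = sum(sr * yr) / sum(sr^2))
  })
  dplyr::bind_rows(out)
}

#' Factorial contrasts on the four run-wise coupling slopes
#'
#' Treats the four rest runs as a 2x2 day-by-time design (runs 1--2 on day
#' 1, runs 3--4 on day 2; runs 1 and 3 before, runs 2 and 4 after the
#' session) and forms the fixed contrasts
#' `main_day  = (b1 + b2) - (b3 + b4)`,
#' `main_time = (b1 + b3) - (b2 + b4)`,
#' `interaction = (b2 - b1) - (b4 - b3)`.
#' The interaction is the screen for coupling changes that are larger on
#' the learning day than on the following day: it is zero for the pure
#' adaptation pattern `[0 1 0 1]` and positive for the consolidation
#' pattern `[0 2 1 1]`. Contrast signs are a fixed convention; group tests
#' are two-sided.
#'
#' @param slopes Either the tibble returned by [run_coupling_slope()] or a
#'   numeric vector of four slopes (runs 1..4 in order).
#' @return One-row tibble with `main_day`, `main_time`, `interaction`.
#' @export
#' @examples
#' factorial_contrasts(c(0, 2, 1, 1))$interaction # 2
factorial_contrasts <- function(slopes) {
  b <- if (is.data.frame(slopes)) {
    slopes$slope[order(slopes$run)]
  } else {
    as.numeric(slopes)
  }
  if (length(b) != 4L || any(!is.finite(b))) {
    abort_restdcm("exactly four finite run slopes are required",
                  "restdcm_parameter_error")
  }
  tibble(
    main_day = (b[1] + b[2]) - (b[3] + b[4]),
    main_time = (b[1] + b[3]) - (b[2] + b[4]),
    interaction = (b[2] - b[1]) - (b[4] - b[3])
  )
}

#' Group test of the day-by-time interaction
#'
#' One-sample t-test of the per-subject interaction contrasts against zero
#' (see [group_ttest()]).
#'
#' @param interactions Numeric vector of per-subject interaction values.
#' @return Tibble with `estimate`, `t`, `df`, `p`, `n`.
#' @export
group_interaction_test <- function(interactions) {
  group_ttest(interactions)
}
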