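#' Generate one subject's trial-level behavior
#'
#' Simulates the alternating-block session: per-trial correctness is
#' Bernoulli with block-wise probability rising from `acc_start` to
#' `acc_asymptote` as a saturating exponential in the (per-condition) block
#' index, and reaction times are truncated-normal with a mean chosen so
#' that the expected block-wise inverse efficiency is exactly
#' `ie_asymptote + ie_amplitude * exp(-learning_rate * block)`. Control
#' blocks are at near-ceiling accuracy with no learning trend. A small
#' fraction of trials is omitted (no response: `rt_s` is `NA`, counted as
#' an error).
#'
#' @param design A [task_design()].
#' @param truth A [ground_truth()] (its `behavior` element is used).
#' @param seed Integer RNG seed.
#' @param subject Subject identifier written into the table.
#' @param start_condition Condition of the first block (`NULL`: derived
#'   from the seed, counterbalancing across subjects).
#' @return Tibble with columns `subject`, `run`, `block` (per-condition
#'   index), `trial`, `condition`, `rt_s`, `correct`.
#' @export
#' @examples
#' tr <- gen_behavior(task_design(), ground_truth(), seed = 1)
#' nrow(tr) # 800
gen_behavior <- function(design, truth, seed, subject = 1L,
                         start_condition = NULL) {
  stopifnot(inherits(design, "task_design"), inherits(truth, "ground_truth"))
  seed <- stopifnot_count(seed, "seed", min = 0L)
  bh <- truth$behavior
  if (is.null(start_condition)) {
    start_condition <- design$conditions[(seed %% 2L) + 1L]
  }
  if (!start_condition %in% design$conditions) {
    abort_restdcm("`start_condition` not among design conditions",
                  "restdcm_parameter_error")
  }
  set.seed(seed)
  nb <- design$n_blocks_per_condition
  nt <- design$trials_per_block
  other <- setdiff(design$conditions, start_condition)
  order_cond <- rep(c(start_condition, other), nb)
  order_block <- rep(seq_len(nb), each = 2L)
  n_total_blocks <- 2L * nb
  blocks_per_run <- ceiling(n_total_blocks / 5L)

  rows <- vector("list", n_total_blocks)
  for (k in seq_len(n_total_blocks)) {
    cond <- order_cond[k]
    x <- order_block[k]
    if (cond == design$conditions[1]) {
      decay <- exp(-bh$learning_rate * x)
      p <- bh$acc_asymptote + (bh$acc_start - bh$acc_asymptote) * decay
      ie <- bh$ie_asymptote + bh$ie_amplitude * decay
      rt_mean <- ie * p
      rt_sd <- bh$rt_sd
    } else {
      p <- bh$control_accuracy
      rt_mean <- bh$control_rt_mean
      rt_sd <- bh$control_rt_sd
    }
    missed <- runif(nt) < bh$miss_rate
    correct <- ifelse(missed, 0L, rbinom(nt, 1L, p))
    rt <- rtruncnorm(nt, rt_mean, rt_sd, 0.05, design$response_window)
    rt[missed] <- NA_real_
    rows[[k]] <- tibble(
      subject = subject,
      run = ceiling(k / blocks_per_run),
      block = x,
      trial = seq_len(nt),
      condition = cond,
      rt_s = rt,
      correct = as.integer(correct)
    )
  }
  dplyr::bind_rows(rows)
}
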