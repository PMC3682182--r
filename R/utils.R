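# internal helpers -----------------------------------------------------------

abort_restdcm <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "restdcm_error"), ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_restdcm(sprintf("`%s` must be a finite scalar number", name),
                  "restdcm_parameter_error")
  }
  if (positive && x <= 0) {
    abort_restdcm(sprintf("`%s` must be positive", name),
                  "restdcm_parameter_error")
  }
  invisible(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort_restdcm(sprintf("`%s` must be an integer >= %d", name, min),
                  "restdcm_parameter_error")
  }
  invisible(as.integer(x))
}

#' Derive a reproducible per-unit seed from a master seed
#'
#' Used by the cohort generator so that every subject (and every stage) gets
#' an independent but fully reproducible RNG stream. Kept below 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param index Positive integer unit index (e.g. subject number).
#' @param stream Small integer offset separating uses within a unit.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, index, stream = 0L) {
  stopifnot_count(master_seed, "master_seed", min = 0L)
  stopifnot_count(index, "index", min = 1L)
  (as.double(master_seed) * 2654435761 + index * 97561 + stream * 7919) %%
    2147483629
}

# draw from a normal truncated to [lo, hi] by inverse-cdf sampling;
# degenerates to clamp(mean) when sd == 0
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (length(sd) == 1L) sd <- rep(sd, n)
  out <- numeric(n)
  zero <- sd <= 0
  out[zero] <- pmin(pmax(mean[zero], lo), hi)
  if (any(!zero)) {
    m <- mean[!zero]; s <- sd[!zero]
    plo <- pnorm(lo, m, s); phi <- pnorm(hi, m, s)
    u <- runif(sum(!zero), plo, phi)
    out[!zero] <- qnorm(u, m, s)
  }
  pmin(pmax(out, lo), hi)
}
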