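# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force Gaussian marginal log-density of a linear state-space model:
# build the full (T*p) x (T*p) covariance of the stacked observations from
# the model matrices and evaluate the multivariate normal density directly.
brute_force_loglik <- function(Y, Phi, Q, C, R, m0, P0) {
  T <- nrow(Y); p <- ncol(Y); n <- nrow(Phi)
  # state covariances Var(x_t) and means
  V <- vector("list", T)
  mu_x <- vector("list", T)
  V[[1]] <- P0
  mu_x[[1]] <- m0
  for (t in seq_len(T - 1)) {
    V[[t + 1]] <- Phi %*% V[[t]] %*% t(Phi) + Q
    mu_x[[t + 1]] <- Phi %*% mu_x[[t]]
  }
  # Cov(x_t, x_s) = Phi^(t-s) V_s for t >= s
  Sigma <- matrix(0, T * p, T * p)
  mu <- numeric(T * p)
  for (t in seq_len(T)) {
    mu[(t - 1) * p + seq_len(p)] <- C %*% mu_x[[t]]
    for (s in seq_len(t)) {
      Cov_x <- V[[s]]
      if (t > s) {
        Pk <- diag(n)
        for (k in seq_len(t - s)) Pk <- Phi %*% Pk
        Cov_x <- Pk %*% Cov_x
      }
      blk <- C %*% Cov_x %*% t(C)
      if (t == s) blk <- blk + R
      Sigma[(t - 1) * p + seq_len(p), (s - 1) * p + seq_len(p)] <- blk
      Sigma[(s - 1) * p + seq_len(p), (t - 1) * p + seq_len(p)] <- t(blk)
    }
  }
  yv <- as.numeric(t(Y)) - mu
  L <- chol(Sigma)
  u <- backsolve(L, yv, transpose = TRUE)
  -0.5 * (length(yv) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
}

# random stable state-space instance for the oracle-equivalence tests
random_ss_instance <- function(n = sample(1:3, 1), p = sample(1:2, 1),
                               T = sample(2:10, 1)) {
  Phi <- matrix(rnorm(n * n), n, n)
  sr <- max(Mod(eigen(Phi, only.values = TRUE)$values))
  Phi <- Phi * (0.9 * runif(1) / max(sr, 0.1))
  Aq <- matrix(rnorm(n * n), n, n)
  Q <- crossprod(Aq) / n + diag(0.05, n)
  C <- matrix(rnorm(p * n), p, n)
  Ar <- matrix(rnorm(p * p), p, p)
  R <- crossprod(Ar) / p + diag(0.1, p)
  P0a <- matrix(rnorm(n * n), n, n)
  P0 <- crossprod(P0a) / n + diag(0.05, n)
  m0 <- rnorm(n)
  # draw Y from the model itself so magnitudes are sensible
  x <- m0 + t(chol(P0)) %*% rnorm(n)
  Y <- matrix(0, T, p)
  for (t in seq_len(T)) {
    Y[t, ] <- C %*% x + t(chol(R)) %*% rnorm(p)
    x <- Phi %*% x + t(chol(Q)) %*% rnorm(n)
  }
  list(Y = Y, Phi = Phi, Q = Q, C = C, R = R, m0 = m0, P0 = P0)
}

# reference R integrator of the nonlinear balloon cascade for a prescribed
# neuronal activity path z(t) on a fixed fine grid (step dt)
balloon_response_r <- function(z_path, dt, hemo = hemo_params()) {
  n <- length(z_path)
  s <- 0; f <- 1; v <- 1; q <- 1
  y <- numeric(n)
  for (t in seq_len(n)) {
    y[t] <- 100 * hemo$V0 * (hemo$k1 * (1 - q) + hemo$k2 * (1 - q / v) +
                               hemo$k3 * (1 - v))
    Ef <- 1 - (1 - hemo$E0)^(1 / f)
    ds <- z_path[t] - hemo$kappa * s - hemo$gamma * (f - 1)
    df <- s
    dv <- (f - v^(1 / hemo$alpha)) / hemo$tau
    dq <- (f * Ef / hemo$E0 - v^(1 / hemo$alpha) * q / v) / hemo$tau
    s <- s + dt * ds; f <- f + dt * df
    v <- v + dt * dv; q <- q + dt * dq
  }
  y
}

# linearized hemodynamic response for the same prescribed z path (fine
# Euler on the 4-state linear operator) — used to check the small-signal
# equivalence of hemo_linear_approx()
linear_response_r <- function(z_path, dt, hemo = hemo_params()) {
  lin <- hemo_linear_approx(hemo)
  x <- numeric(4)
  y <- numeric(length(z_path))
  for (t in seq_along(z_path)) {
    y[t] <- as.numeric(lin$c_out %*% x)
    x <- x + dt * (lin$H %*% x + lin$b_in * z_path[t])
  }
  y
}

# small scan/truth shortcuts for cheap tests
quick_scan <- function(rest_volumes = 60L, ...) {
  scan_config(rest_volumes = rest_volumes, ...)
}
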