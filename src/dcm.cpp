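// Numerical core for the bilinear DCM machinery: exact discretization of a
// continuous-time linear-Gaussian system, steady-state Lyapunov solve,
// Kalman-filter marginal likelihood, and the nonlinear balloon-model
// integrator used by the synthetic-data generators.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact discretization of dx/dt = F x + w, cov(w) = Lc (continuous spectral
// density), over a step dt, via Van Loan's augmented matrix exponential.
// Returns the transition matrix Phi = expm(F dt) and the discrete innovation
// covariance Q = int_0^dt expm(F s) Lc expm(F' s) ds.
// [[Rcpp::export]]
Rcpp::List vanloan_discretize(const arma::mat& F, const arma::mat& Lc,
                              const double dt) {
  const uword n = F.n_rows;
  mat M(2 * n, 2 * n, fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = -F * dt;
  M.submat(0, n, n - 1, 2 * n - 1) = Lc * dt;
  M.submat(n, n, 2 * n - 1, 2 * n - 1) = F.t() * dt;
  mat E = expmat(M);
  mat F4 = E.submat(n, n, 2 * n - 1, 2 * n - 1);
  mat F3 = E.submat(0, n, n - 1, 2 * n - 1);
  mat Phi = F4.t();
  mat Q = Phi * F3;
  Q = 0.5 * (Q + Q.t());  // enforce symmetry against roundoff
  return Rcpp::List::create(Rcpp::Named("Phi") = Phi, Rcpp::Named("Q") = Q);
}

// Stationary covariance P = Phi P Phi' + Q by the doubling algorithm.
// Requires spectral radius of Phi < 1.
// [[Rcpp::export]]
arma::mat dlyap_doubling(const arma::mat& Phi, const arma::mat& Q,
                         const int max_iter = 60, const double tol = 1e-13) {
  mat A = Phi;
  mat P = Q;
  for (int i = 0; i < max_iter; ++i) {
    mat P_new = P + A * P * A.t();
    mat A_new = A * A;
    double delta = norm(P_new - P, "fro");
    P = 0.5 * (P_new + P_new.t());
    A = A_new;
    if (delta < tol * (1.0 + norm(P, "fro"))) break;
  }
  return P;
}

// Gaussian marginal log-likelihood of one run of observations under a
// time-invariant linear state-space model, by the prediction-error
// decomposition. Y is T x p (rows are time points).
// [[Rcpp::export]]
double kalman_loglik_cpp(const arma::mat& Y, const arma::mat& Phi,
                         const arma::mat& Q, const arma::mat& C,
                         const arma::mat& R, const arma::vec& m0,
                         const arma::mat& P0) {
  const uword T = Y.n_rows;
  const uword p = Y.n_cols;
  const double log2pi = std::log(2.0 * datum::pi);
  vec m = m0;
  mat P = P0;
  double ll = 0.0;
  for (uword t = 0; t < T; ++t) {
    vec e = Y.row(t).t() - C * m;
    mat PCt = P * C.t();
    mat S = C * PCt + R;
    S = 0.5 * (S + S.t());
    mat Sc;
    if (!chol(Sc, S)) return -datum::inf;
    double logdet = 2.0 * accu(log(Sc.diag()));
    vec u = solve(trimatl(Sc.t()), e);
    ll += -0.5 * (p * log2pi + logdet + dot(u, u));
    // update; gain via the Cholesky factor of S (already verified PD)
    mat K = solve(trimatu(Sc), solve(trimatl(Sc.t()), PCt.t())).t();
    m = m + K * e;
    P = P - K * S * K.t();
    P = 0.5 * (P + P.t());
    // predict
    m = Phi * m;
    P = Phi * P * Phi.t() + Q;
    P = 0.5 * (P + P.t());
  }
  return ll;
}

// Euler-Maruyama integration of the two-(or n-)region bilinear neuronal model
// driven by an AR(1) innovation process, cascaded through the nonlinear
// balloon hemodynamic model, sampled at the TR.
//   dz/dt = A z + w(t),  w AR(1) with per-step coefficient rho and
//   innovation sd sigma_z * (1 - rho) / sqrt(dt) (flat low-frequency spectral
//   density sigma_z^2; rho = 0 recovers white noise).
// eps: (burn_steps + n_steps) x nreg standard-normal draws supplied by the
// caller so that all randomness flows through R's RNG.
// hemo: kappa, gamma, tau, alpha, E0, V0 (k1,k2,k3 derived).
// Output: n_vols x nreg noise-free percent-signal-change BOLD.
// [[Rcpp::export]]
arma::mat balloon_simulate_cpp(const arma::mat& A, const arma::mat& eps,
                               const double sigma_z, const double rho,
                               const double dt, const double tr,
                               const int n_vols, const int burn_steps,
                               const arma::vec& hemo) {
  const uword nreg = A.n_rows;
  const double kappa = hemo(0), gamma = hemo(1), tau = hemo(2),
               alpha = hemo(3), E0 = hemo(4), V0 = hemo(5);
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const uword n_steps = eps.n_rows;
  const double sig_e = sigma_z * (1.0 - rho) / std::sqrt(dt);

  vec z(nreg, fill::zeros), w(nreg, fill::zeros);
  vec s(nreg, fill::zeros), f(nreg, fill::ones), v(nreg, fill::ones),
      q(nreg, fill::ones);
  mat out(n_vols, nreg, fill::zeros);

  // volume k is read at time k * tr past the end of burn-in
  uword next_vol = 0;
  uword next_idx = burn_steps;
  for (uword t = 0; t < n_steps; ++t) {
    if (next_vol < (uword)n_vols && t == next_idx) {
      for (uword r = 0; r < nreg; ++r) {
        out(next_vol, r) = 100.0 * V0 *
          (k1 * (1.0 - q(r)) + k2 * (1.0 - q(r) / v(r)) + k3 * (1.0 - v(r)));
      }
      ++next_vol;
      next_idx = burn_steps + (uword)std::lround(next_vol * tr / dt);
    }
    w = rho * w + sig_e * eps.row(t).t();
    vec dz = A * z + w;
    for (uword r = 0; r < nreg; ++r) {
      double vr = std::max(v(r), 1e-9);
      double fr = std::max(f(r), 1e-9);
      double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / fr);
      double ds = z(r) - kappa * s(r) - gamma * (f(r) - 1.0);
      double df = s(r);
      double dv = (f(r) - std::pow(vr, 1.0 / alpha)) / tau;
      double dq = (f(r) * Ef / E0 - std::pow(vr, 1.0 / alpha) * q(r) / vr) / tau;
      s(r) += dt * ds;
      f(r) += dt * df;
      v(r) += dt * dv;
      q(r) += dt * dq;
    }
    z += dt * dz;
    if (!z.is_finite() || !v.is_finite() || !q.is_finite()) {
      Rcpp::stop("balloon integration diverged at step %d", (int)t);
    }
  }
  if (next_vol < (uword)n_vols) {
    Rcpp::stop("integration grid too short for requested volumes");
  }
  return out;
}

// Full negative log joint (likelihood + Gaussian prior) for one subject's
// four runs, evaluated entirely in compiled code. theta layout:
// [a_forward, a_backward, b_1..b_k (modulator-major, connection-minor),
//  log_sigma_z, log_sigma_obs_1, log_sigma_obs_2].
// weights: n_mod x n_runs modulator run weights; conn_fwd: logical vector
// over connections (true = forward, i.e. A(1,0); false = A(0,1)).
// Hlin/b_in/c_out: linearized hemodynamic operator (4 states per region).
// Returns 1e9-scale barrier values outside the stable/sane region.
// lambda > 0 adds two Ornstein-Uhlenbeck innovation states with decay
// lambda (1/s) driving the neuronal states, modeling temporally smooth
// endogenous fluctuations; lambda = 0 uses white-noise driving.
// [[Rcpp::export]]
double neg_log_joint_cpp(const arma::vec& theta, const Rcpp::List& Ylist,
                         const arma::mat& weights,
                         const arma::uvec& conn_fwd,
                         const double a_self, const arma::mat& Hlin,
                         const arma::vec& b_in, const arma::rowvec& c_out,
                         const double tr, const arma::vec& prior_mean,
                         const arma::vec& prior_sd,
                         const double lambda = 0.0) {
  const uword n_mod = weights.n_rows;
  const uword n_con = conn_fwd.n_elem;
  const uword n_runs = Ylist.size();
  const uword d = theta.n_elem;
  // guard against absurd excursions during line search
  for (uword i = 0; i < d; ++i) {
    double zscore = std::abs(theta(i) - prior_mean(i)) / prior_sd(i);
    if (zscore > 8.0) return 1e9 * (1.0 + zscore - 8.0);
  }
  const double sigma_z = std::exp(theta(d - 3));
  const double so1 = std::exp(theta(d - 2));
  const double so2 = std::exp(theta(d - 1));

  // run-effective 2x2 neuronal matrices + stability barrier
  std::vector<mat> Aeff(n_runs);
  double worst = -datum::inf;
  for (uword r = 0; r < n_runs; ++r) {
    mat A(2, 2);
    A(0, 0) = A(1, 1) = a_self;
    A(1, 0) = theta(0);
    A(0, 1) = theta(1);
    uword k = 2;
    for (uword j = 0; j < n_mod; ++j) {
      for (uword c = 0; c < n_con; ++c, ++k) {
        double add = weights(j, r) * theta(k);
        if (conn_fwd(c)) A(1, 0) += add; else A(0, 1) += add;
      }
    }
    // eigenvalues of 2x2: tr/2 +- sqrt(tr^2/4 - det); max real part
    double trc = A(0, 0) + A(1, 1);
    double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
    double disc = trc * trc / 4.0 - det;
    double max_re = (disc >= 0) ? trc / 2.0 + std::sqrt(disc) : trc / 2.0;
    worst = std::max(worst, max_re);
    Aeff[r] = A;
  }
  if (worst >= -1e-3) return 1e9 * (1.0 + std::max(worst, 0.0));

  // shared structure; with colored innovations the latent state is
  // [z (2), w (2), hemo (4 per region)], otherwise [z (2), hemo (8)]
  const bool colored = lambda > 0.0;
  const uword off = colored ? 4 : 2;  // where the hemo blocks start
  const uword n = off + 8;
  mat R(2, 2, fill::zeros);
  R(0, 0) = so1 * so1;
  R(1, 1) = so2 * so2;
  mat C(2, n, fill::zeros);
  for (uword reg = 0; reg < 2; ++reg) {
    C.submat(reg, off + reg * 4, reg, off + 3 + reg * 4) = c_out;
  }
  mat Lc(n, n, fill::zeros);
  if (colored) {
    // OU innovations with low-frequency spectral density sigma_z^2
    Lc(2, 2) = Lc(3, 3) = sigma_z * sigma_z * lambda * lambda;
  } else {
    Lc(0, 0) = Lc(1, 1) = sigma_z * sigma_z;
  }
  vec m0(n, fill::zeros);

  double ll = 0.0;
  for (uword r = 0; r < n_runs; ++r) {
    mat F(n, n, fill::zeros);
    F.submat(0, 0, 1, 1) = Aeff[r];
    if (colored) {
      F(0, 2) = F(1, 3) = 1.0;
      F(2, 2) = F(3, 3) = -lambda;
    }
    for (uword reg = 0; reg < 2; ++reg) {
      F.submat(off + reg * 4, off + reg * 4,
               off + 3 + reg * 4, off + 3 + reg * 4) = Hlin;
      F.submat(off + reg * 4, reg, off + 3 + reg * 4, reg) = b_in;
    }
    // discretize: Phi = expm(F tr); for stable F the stationary covariance
    // P solves the continuous Lyapunov equation F P + P F' + Lc = 0, and
    // the discrete innovation covariance is Q = P - Phi P Phi'
    mat Phi = expmat(F * tr);
    mat P0;
    if (!syl(P0, F, F.t(), Lc)) return 1e10;
    P0 = 0.5 * (P0 + P0.t());
    mat Q = P0 - Phi * P0 * Phi.t();
    Q = 0.5 * (Q + Q.t());
    double lr = kalman_loglik_cpp(Rcpp::as<arma::mat>(Ylist[r]), Phi, Q, C,
                                  R, m0, P0);
    if (!std::isfinite(lr)) return 1e10;
    ll += lr;
  }
  double lp = 0.0;
  const double log2pi = std::log(2.0 * datum::pi);
  for (uword i = 0; i < d; ++i) {
    double z = (theta(i) - prior_mean(i)) / prior_sd(i);
    lp += -0.5 * (log2pi + 2.0 * std::log(prior_sd(i)) + z * z);
  }
  double v = -(ll + lp);
  return std::isfinite(v) ? v : 1e10;
}
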