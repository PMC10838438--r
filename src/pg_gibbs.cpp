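// Gibbs sampler for Bayesian logistic regression with Polya-Gamma data
// augmentation (Polson, Scott & Windle). Coefficient priors are either
// Laplace(0, b) via the Park-Casella exponential scale mixture, or
// Normal(0, sd). The intercept always carries a Normal(0, 1) prior and is
// handled as the first design column with fixed prior precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TRUNC = 0.64;
static const double TRUNC_RECIP = 1.0 / TRUNC;

// Piecewise coefficients a_n(x) of the Jacobi density alternating series.
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  } else {
    return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np5 * np5 / x);
  }
}

// P(sample from the truncated-exponential branch) for the Devroye mixture.
static double mass_texpon(double z) {
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / TRUNC) * (TRUNC * z - 1.0);
  double a = -std::sqrt(1.0 / TRUNC) * (TRUNC * z + 1.0);
  double x0 = std::log(fz) + fz * TRUNC;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(mu, lambda = 1) truncated to (0, TRUNC].
static double rtigauss(double z) {
  z = std::fabs(z);
  double x = TRUNC + 1.0;
  if (TRUNC_RECIP > z) { // mu = 1/z > t: rejection from truncated chi-like proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1 = exp_rand();
      double e2 = exp_rand();
      while (e1 * e1 > 2.0 * e2 / TRUNC) {
        e1 = exp_rand();
        e2 = exp_rand();
      }
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > TRUNC) {
      double y = norm_rand();
      y = y * y;
      double half_mu = 0.5 * mu;
      double mu_y = mu * y;
      x = mu + half_mu * mu_y - half_mu * std::sqrt(4.0 * mu_y + mu_y * mu_y);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// One PG(1, z) draw by Devroye's alternating-series rejection sampler.
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  while (true) {
    double x;
    if (unif_rand() < mass_texpon(z)) {
      x = TRUNC + exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    bool decided = false, accept = false;
    while (!decided) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) { decided = true; accept = true; }
      } else {
        s += a_coef(n, x);
        if (y > s) { decided = true; accept = false; }
      }
      if (n > 1000) { decided = true; accept = true; } // series converges long before this
    }
    if (accept) return 0.25 * x;
  }
}

// Inverse-Gaussian(mu, lambda) draw (Michael, Schucany & Haas).
static double rinvgauss(double mu, double lambda) {
  double y = norm_rand();
  y = y * y;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12 * mu; // floating-point cancellation guard
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

//' @noRd
// [[Rcpp::export(name = ".rpg_vec")]]
Rcpp::NumericVector rpg_vec(Rcpp::NumericVector z) {
  int n = z.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".pg_gibbs_chain")]]
Rcpp::NumericMatrix pg_gibbs_chain(const arma::mat& X, const arma::vec& y,
                                   std::string prior, double scale,
                                   double intercept_sd, int warmup, int iter) {
  // X includes the leading intercept column of ones.
  const int n = X.n_rows;
  const int p = X.n_cols; // 1 + number of features
  arma::vec beta(p, arma::fill::zeros);
  arma::vec kappa = y - 0.5;
  arma::vec Xtk = X.t() * kappa;
  arma::vec prior_prec(p);
  prior_prec[0] = 1.0 / (intercept_sd * intercept_sd);
  const bool laplace = (prior == "laplace");
  const double lambda = 1.0 / scale;            // Laplace rate
  const double normal_prec = 1.0 / (scale * scale); // when prior == "normal"
  for (int j = 1; j < p; ++j)
    prior_prec[j] = laplace ? 1.0 : normal_prec; // Laplace precisions drawn below

  Rcpp::NumericMatrix draws(iter, p);
  arma::vec psi(n), omega(n);
  const int total = warmup + iter;
  for (int s = 0; s < total; ++s) {
    // omega_i | beta ~ PG(1, x_i' beta)
    psi = X * beta;
    for (int i = 0; i < n; ++i) omega[i] = rpg1(psi[i]);
    // Laplace scale-mixture variances: 1/tau_j^2 ~ IG(lambda/|beta_j|, lambda^2)
    if (laplace) {
      for (int j = 1; j < p; ++j) {
        double bj = std::fabs(beta[j]);
        if (bj < 1e-10) bj = 1e-10;
        double inv_tau2 = rinvgauss(lambda / bj, lambda * lambda);
        prior_prec[j] = inv_tau2;
      }
    }
    // beta | omega ~ N(V X' kappa, V), V = (X' Omega X + D^-1)^-1
    arma::mat prec = X.t() * (X.each_col() % omega);
    prec.diag() += prior_prec;
    arma::mat L = arma::chol(prec, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), Xtk));
    arma::vec zdraw(p);
    for (int j = 0; j < p; ++j) zdraw[j] = norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), zdraw);
    if (s >= warmup) {
      for (int j = 0; j < p; ++j) draws(s - warmup, j) = beta[j];
    }
  }
  return draws;
}
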