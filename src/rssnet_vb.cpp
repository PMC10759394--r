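// Coordinate-ascent variational inference for the spike-and-slab model on
// GWAS summary statistics within one LD block.
//
// Model (per block): betahat ~ N(S R S^{-1} beta, S R S) with S = diag(se),
// R the reference LD; beta_j ~ pi_j N(0, sigma2_j) + (1 - pi_j) delta_0.
// The variational family is fully factorized per SNP:
// q(beta_j) = alpha_j N(mu_j, s2_j) + (1 - alpha_j) delta_0.
//
// Inputs are the transformed quantities Omega = S^{-1} R S^{-1} and
// y = betahat / se^2; the data-dependent constant of the evidence lower
// bound (involving R^{-1}) is added on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double xlogx(double x) {
  return (x > 0.0) ? x * std::log(x) : 0.0;
}

// [[Rcpp::export(name = ".vb_block")]]
List vb_block(const arma::mat& Omega, const arma::vec& y,
              const arma::vec& sigma2, const arma::vec& log_odds,
              const arma::uvec& update_order,
              arma::vec alpha, arma::vec mu,
              double tol, int max_iter) {
  const arma::uword p = y.n_elem;
  arma::vec d = Omega.diag();
  arma::vec s2 = 1.0 / (d + 1.0 / sigma2);
  // log pi and log(1 - pi) from the natural-log prior odds, stably
  arma::vec log_pi(p), log_1mpi(p);
  for (arma::uword j = 0; j < p; ++j) {
    double lo = log_odds[j];
    log_pi[j]   = -std::log1p(std::exp(-lo));
    log_1mpi[j] = -std::log1p(std::exp(lo));
  }
  arma::vec amu = alpha % mu;
  arma::vec Xr = Omega * amu;   // running Omega * (alpha mu)
  std::vector<double> trace;
  trace.reserve(64);
  double elbo_old = -arma::datum::inf;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (arma::uword k = 0; k < p; ++k) {
      arma::uword j = update_order[k];
      double amu_old = amu[j];
      double rj = Xr[j] - d[j] * amu_old;   // sum_{k != j} Omega_jk amu_k
      double mj = s2[j] * (y[j] - rj);
      mu[j] = mj;
      double lo = log_odds[j] +
        0.5 * (std::log(s2[j] / sigma2[j]) + mj * mj / s2[j]);
      double aj = 1.0 / (1.0 + std::exp(-lo));
      alpha[j] = aj;
      double amu_new = aj * mj;
      if (amu_new != amu_old) {
        Xr += Omega.col(j) * (amu_new - amu_old);
        amu[j] = amu_new;
      }
    }
    // evidence lower bound (data constant added on the R side)
    double fit = arma::dot(y, amu) - 0.5 * arma::dot(amu, Xr);
    double kl = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      double aj = alpha[j];
      fit -= 0.5 * d[j] * (aj * (s2[j] + mu[j] * mu[j]) - amu[j] * amu[j]);
      kl += xlogx(aj) + xlogx(1.0 - aj)
          - aj * log_pi[j] - (1.0 - aj) * log_1mpi[j]
          - 0.5 * aj * (1.0 + std::log(s2[j] / sigma2[j])
                        - (s2[j] + mu[j] * mu[j]) / sigma2[j]);
    }
    double elbo = fit - kl;
    trace.push_back(elbo);
    if (std::fabs(elbo - elbo_old) <= tol * (1.0 + std::fabs(elbo))) {
      converged = true;
      break;
    }
    elbo_old = elbo;
  }
  return List::create(_["alpha"] = alpha, _["mu"] = mu, _["s2"] = s2,
                      _["elbo"] = trace.back(),
                      _["elbo_trace"] = trace,
                      _["converged"] = converged,
                      _["n_iter"] = (int)trace.size());
}
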