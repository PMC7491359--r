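#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the one-way g-prior model (see R/marginal.R for the
// model statement). All conditionals are conjugate:
//   beta = (mu0, alpha) | sigma2, g  ~  Normal
//   sigma2 | beta, g                 ~  Inverse-Gamma
//   g | beta, sigma2                 ~  Inverse-Gamma
// Uses R's RNG so draws are reproducible via set.seed() on the R side.
// grp is 0-based; Q is the G x (G-1) sum-to-zero basis; fixed_g > 0 freezes
// g at that value (degenerate prior). Returns kept draws with columns
// (mu_1..mu_G, sigma2, g).
// [[Rcpp::export]]
arma::mat gibbs_gprior(const arma::vec& y, const arma::uvec& grp, int G,
                       const arma::mat& Q, double r, int iterations,
                       int warmup, double fixed_g) {
  const int N = y.n_elem;
  const int p = Q.n_cols;
  const int q = p + 1;

  // sufficient statistics
  arma::vec ng(G, arma::fill::zeros), sg(G, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    ng(grp(i)) += 1.0;
    sg(grp(i)) += y(i);
  }
  const double yty = arma::dot(y, y);

  // X_f = [1, X Q] with X the N x G group indicator matrix
  arma::mat XtX(q, q);
  XtX(0, 0) = N;
  arma::rowvec nQ = ng.t() * Q;
  XtX.submat(0, 1, 0, q - 1) = nQ;
  XtX.submat(1, 0, q - 1, 0) = nQ.t();
  arma::mat QnQ = Q.t() * (Q.each_col() % ng);
  XtX.submat(1, 1, q - 1, q - 1) = QnQ;
  arma::vec Xty(q);
  Xty(0) = arma::accu(y);
  Xty.subvec(1, q - 1) = Q.t() * sg;

  double sigma2 = arma::var(y);
  if (!(sigma2 > 0)) sigma2 = 1.0;
  double g = (fixed_g > 0) ? fixed_g : r * r;
  arma::vec beta(q, arma::fill::zeros);

  const int keep = iterations - warmup;
  arma::mat out(keep, G + 2);

  for (int it = 0; it < iterations; ++it) {
    // beta | sigma2, g
    arma::mat M = XtX;
    for (int j = 1; j < q; ++j) M(j, j) += 1.0 / g;
    arma::mat L = arma::chol(M, "lower");
    arma::vec m = arma::solve(arma::trimatu(L.t()),
                              arma::solve(arma::trimatl(L), Xty));
    arma::vec z(q);
    for (int j = 0; j < q; ++j) z(j) = R::norm_rand();
    beta = m + std::sqrt(sigma2) * arma::solve(arma::trimatu(L.t()), z);

    // sigma2 | beta, g  (Jeffreys prior contributes the extra 1/sigma2)
    arma::vec alpha = beta.subvec(1, q - 1);
    double rss = yty - 2.0 * arma::dot(beta, Xty) +
                 arma::as_scalar(beta.t() * XtX * beta);
    if (rss < 0) rss = 0;
    const double aa = arma::dot(alpha, alpha);
    sigma2 = 0.5 * (rss + aa / g) / R::rgamma(0.5 * (N + p), 1.0);

    // g | alpha, sigma2 under g ~ InvGamma(1/2, r^2/2)
    if (fixed_g <= 0) {
      g = 0.5 * (r * r + aa / sigma2) / R::rgamma(0.5 * (p + 1), 1.0);
    }

    if (it >= warmup) {
      arma::vec mu = beta(0) + Q * alpha;
      for (int k = 0; k < G; ++k) out(it - warmup, k) = mu(k);
      out(it - warmup, G) = sigma2;
      out(it - warmup, G + 1) = g;
    }
  }
  return out;
}
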