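#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One Gibbs chain for the Gaussian random-intercept model
//   y_k = w_k' beta + s_{id_k} + eps_k,  s_i ~ N(0, s2s),  eps_k ~ N(0, s2e)
// with beta_j ~ N(beta_mean, beta_var) iid and s2s, s2e ~ InvGamma(shape, scale).
// All randomness comes from R's RNG stream (RNGScope via Rcpp attributes), so
// chains are reproducible from set.seed() on the R side.
//
// id is 0-based and indexes individuals 0..n_ind-1; individuals without
// observations receive prior draws for s_i (needed when a fold removes the
// last cell of an individual, which stratified folds normally prevent).
// [[Rcpp::export]]
List gibbs_chain(const arma::vec& y, const arma::mat& W, const arma::uvec& id,
                 const int n_ind, const double beta_mean, const double beta_var,
                 const double var_shape, const double var_scale,
                 const int n_iter, const int burn_in, const int thin,
                 const arma::vec& beta_init, const double s2s_init,
                 const double s2e_init) {
  const int n = y.n_elem;
  const int p = W.n_cols;
  const arma::mat WtW = W.t() * W;

  arma::vec n_obs(n_ind, arma::fill::zeros);
  for (int k = 0; k < n; ++k) n_obs(id(k)) += 1.0;

  arma::vec beta = beta_init;
  arma::vec s(n_ind, arma::fill::zeros);
  double s2s = s2s_init, s2e = s2e_init;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(n_keep, p);
  arma::mat s_draws(n_keep, n_ind);
  arma::vec s2s_draws(n_keep), s2e_draws(n_keep);

  arma::vec z(p), mu(n), r(n), rsum(n_ind);
  int keep = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // beta | s, variances: Gaussian with precision W'W/s2e + I/beta_var
    for (int k = 0; k < n; ++k) r(k) = y(k) - s(id(k));
    arma::mat A = WtW / s2e;
    A.diag() += 1.0 / beta_var;
    arma::vec b = W.t() * r / s2e;
    b += beta_mean / beta_var;
    arma::mat U = arma::chol(A);  // A = U'U, U upper triangular
    arma::vec m = arma::solve(arma::trimatu(U),
                              arma::solve(arma::trimatl(U.t()), b));
    for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
    beta = m + arma::solve(arma::trimatu(U), z);

    // s_i | beta, variances: independent Gaussians
    mu = W * beta;
    rsum.zeros();
    for (int k = 0; k < n; ++k) rsum(id(k)) += y(k) - mu(k);
    for (int i = 0; i < n_ind; ++i) {
      const double prec = n_obs(i) / s2e + 1.0 / s2s;
      const double mean_i = rsum(i) / s2e / prec;
      s(i) = mean_i + R::norm_rand() / std::sqrt(prec);
    }

    // variance components | rest: inverse-gamma
    s2s = 1.0 / R::rgamma(var_shape + 0.5 * n_ind,
                          1.0 / (var_scale + 0.5 * arma::dot(s, s)));
    double rss = 0.0;
    for (int k = 0; k < n; ++k) {
      const double e = y(k) - mu(k) - s(id(k));
      rss += e * e;
    }
    s2e = 1.0 / R::rgamma(var_shape + 0.5 * n, 1.0 / (var_scale + 0.5 * rss));

    if (it > burn_in && (it - burn_in) % thin == 0) {
      beta_draws.row(keep) = beta.t();
      s_draws.row(keep) = s.t();
      s2s_draws(keep) = s2s;
      s2e_draws(keep) = s2e;
      ++keep;
    }
  }

  return List::create(_["beta"] = beta_draws, _["s"] = s_draws,
                      _["sigma2_s"] = s2s_draws, _["sigma2_eps"] = s2e_draws);
}
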