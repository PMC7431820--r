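#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Full-information Gaussian log-likelihood over twin pairs.
//
// y     : n x 4 observation matrix, slot order (twin1.t1, twin1.t2,
//         twin2.t1, twin2.t2); NA/NaN marks an unobserved slot.
// mu    : n x 4 matrix of model-implied slot means.
// sigma : 4 x 4 x G cube of pair covariance matrices, one slice per
//         (zygosity, country) group.
// grp   : length-n vector of 0-based slice indices.
//
// Each pair contributes the multivariate-normal log-density of its
// observed subvector (marginalization, not imputation). A non-positive-
// definite observed submatrix makes the whole likelihood -Inf so the
// optimizer backs away from that region.

// [[Rcpp::export]]
double fiml_loglik_cpp(const arma::mat& y, const arma::mat& mu,
                       const arma::cube& sigma, const arma::uvec& grp) {
  static const double LOG2PI = 1.837877066409345483560659472811;
  const arma::uword n = y.n_rows;
  double total = 0.0;

  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec obs(4);
    arma::uword k = 0;
    for (arma::uword j = 0; j < 4; ++j)
      if (arma::is_finite(y(i, j))) obs(k++) = j;
    if (k == 0) continue;  // rejected upstream; defensive
    obs = obs.head(k);

    arma::mat S = sigma.slice(grp(i)).submat(obs, obs);
    arma::vec r(k);
    for (arma::uword j = 0; j < k; ++j) r(j) = y(i, obs(j)) - mu(i, obs(j));

    arma::mat L;
    if (!arma::chol(L, S, "lower"))
      return -std::numeric_limits<double>::infinity();
    arma::vec z = arma::solve(arma::trimatl(L), r);
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    total += -0.5 * (static_cast<double>(k) * LOG2PI + logdet +
                     arma::dot(z, z));
  }
  return total;
}

// Per-pair contributions (same contract), used for diagnostics and for
// flagging pairs with numerically singular observed submatrices.
// [[Rcpp::export]]
Rcpp::NumericVector fiml_loglik_pairs_cpp(const arma::mat& y,
                                          const arma::mat& mu,
                                          const arma::cube& sigma,
                                          const arma::uvec& grp) {
  static const double LOG2PI = 1.837877066409345483560659472811;
  const arma::uword n = y.n_rows;
  Rcpp::NumericVector out(n);

  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec obs(4);
    arma::uword k = 0;
    for (arma::uword j = 0; j < 4; ++j)
      if (arma::is_finite(y(i, j))) obs(k++) = j;
    if (k == 0) { out[i] = NA_REAL; continue; }
    obs = obs.head(k);

    arma::mat S = sigma.slice(grp(i)).submat(obs, obs);
    arma::vec r(k);
    for (arma::uword j = 0; j < k; ++j) r(j) = y(i, obs(j)) - mu(i, obs(j));

    arma::mat L;
    if (!arma::chol(L, S, "lower")) { out[i] = R_NegInf; continue; }
    arma::vec z = arma::solve(arma::trimatl(L), r);
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    out[i] = -0.5 * (static_cast<double>(k) * LOG2PI + logdet +
                     arma::dot(z, z));
  }
  return out;
}
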