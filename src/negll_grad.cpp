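#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Negative FIML log-likelihood and its analytic gradient for the
// bivariate Cholesky twin model, used by the optimizer.
//
// Parameter layout (full vector, fixed entries held at 0/1 by the R
// wrapper): paths (a11,a21,a22,s11,s21,s22,e11,e21,e22), country-1 SD
// scalars (k1,k2), mean coefficients beta (length = number of design
// slices in D).
//
// Groups (grp): 0 = MZ country 0, 1 = DZ country 0, 2 = MZ country 1,
// 3 = DZ country 1. Cross-twin weights: A -> 1 / 0.5; second source ->
// 1 / wSdz (1 for C, 0.25 for D); E -> 0.
//
// For a pair with observed index set o, mean mu_o and covariance S:
//   d(ll)/d(theta_cov) = 0.5 * (q' dS q - tr(P dS)),  q = S^-1 r, P = S^-1
//   d(ll)/d(beta_j)    = D_j(i, o) . q
// Sigma for country 1 is M elementwise-scaled by kvec kvec', so k
// derivatives scale M by (u kvec' + kvec u') with u the occasion mask.

static inline arma::mat comp_cov(double l11, double l21, double l22) {
  arma::mat m(2, 2);
  m(0, 0) = l11 * l11; m(0, 1) = l11 * l21;
  m(1, 0) = l11 * l21; m(1, 1) = l21 * l21 + l22 * l22;
  return m;
}

static inline arma::mat dcomp(double l11, double l21, int which) {
  arma::mat m(2, 2, arma::fill::zeros);
  if (which == 0) { m(0, 0) = 2 * l11; m(0, 1) = m(1, 0) = l21; }
  else if (which == 1) { m(0, 1) = m(1, 0) = l11; m(1, 1) = 2 * l21; }
  // l22 handled by caller (needs l22)
  return m;
}

static inline arma::mat pair_block(const arma::mat& W, const arma::mat& C) {
  arma::mat M(4, 4);
  M.submat(0, 0, 1, 1) = W; M.submat(2, 2, 3, 3) = W;
  M.submat(0, 2, 1, 3) = C; M.submat(2, 0, 3, 1) = C;
  return M;
}

// [[Rcpp::export]]
List twin_negll_grad_cpp(const arma::vec& paths, const arma::vec& k,
                         const arma::vec& beta, const arma::mat& y,
                         const arma::cube& D, const arma::uvec& grp,
                         double wSdz, bool hasS, bool two_countries) {
  static const double LOG2PI = 1.837877066409345483560659472811;
  const arma::uword n = y.n_rows;
  const arma::uword pmu = D.n_slices;
  const int ncov = 11;  // 9 paths + 2 scalars

  // component matrices
  arma::mat A = comp_cov(paths(0), paths(1), paths(2));
  arma::mat S2 = comp_cov(paths(3), paths(4), paths(5));
  arma::mat E = comp_cov(paths(6), paths(7), paths(8));
  arma::mat W = A + S2 + E;

  // group covariances and their chol factors
  arma::cube sigma(4, 4, 4);
  arma::vec kvec = {k(0), k(1), k(0), k(1)};
  arma::mat kk = kvec * kvec.t();
  double wA[4] = {1.0, 0.5, 1.0, 0.5};
  double wS[4] = {1.0, wSdz, 1.0, wSdz};
  for (int g = 0; g < 4; ++g) {
    arma::mat C = wA[g] * A;
    if (hasS) C += wS[g] * S2;
    arma::mat M = pair_block(W, C);
    sigma.slice(g) = (g >= 2) ? arma::mat(M % kk) : M;
  }

  // derivative of sigma w.r.t. each of the 11 covariance parameters,
  // per group: dsig[g * ncov + j]
  std::vector<arma::mat> dsig(4 * ncov);
  for (int g = 0; g < 4; ++g) {
    for (int s = 0; s < 3; ++s) {        // source: 0=A, 1=S, 2=E
      double l11 = paths(3 * s), l21 = paths(3 * s + 1),
             l22 = paths(3 * s + 2);
      double w = (s == 0) ? wA[g] : (s == 1 ? (hasS ? wS[g] : 0.0) : 0.0);
      for (int which = 0; which < 3; ++which) {
        arma::mat dC(2, 2, arma::fill::zeros);
        if (which == 2) dC(1, 1) = 2 * l22;
        else dC = dcomp(l11, l21, which);
        arma::mat dM = pair_block(dC, w * dC);
        if (g >= 2) dM = dM % kk;
        dsig[g * ncov + 3 * s + which] = dM;
      }
    }
    // k1, k2
    for (int t = 0; t < 2; ++t) {
      if (g >= 2 && two_countries) {
        arma::vec u(4, arma::fill::zeros);
        u(t) = 1.0; u(t + 2) = 1.0;
        arma::mat dkk = u * kvec.t() + kvec * u.t();
        arma::mat C = wA[g] * A;
        if (hasS) C += wS[g] * S2;
        dsig[g * ncov + 9 + t] = pair_block(W, C) % dkk;
      } else {
        dsig[g * ncov + 9 + t] = arma::mat(4, 4, arma::fill::zeros);
      }
    }
  }

  // mean matrix
  arma::mat mu(n, 4, arma::fill::zeros);
  for (arma::uword j = 0; j < pmu; ++j) mu += beta(j) * D.slice(j);

  double negll = 0.0;
  arma::vec grad(ncov + pmu, arma::fill::zeros);  // d(-ll)/d(theta)

  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec obs(4);
    arma::uword kk2 = 0;
    for (arma::uword j = 0; j < 4; ++j)
      if (arma::is_finite(y(i, j))) obs(kk2++) = j;
    if (kk2 == 0) continue;
    obs = obs.head(kk2);
    int g = grp(i);

    arma::mat Ssub = sigma.slice(g).submat(obs, obs);
    arma::vec r(kk2);
    for (arma::uword j = 0; j < kk2; ++j) r(j) = y(i, obs(j)) - mu(i, obs(j));

    arma::mat L;
    if (!arma::chol(L, Ssub, "lower")) {
      return List::create(_["value"] = 1e10,
                          _["grad"] = NumericVector(ncov + pmu));
    }
    arma::vec q = arma::solve(arma::trimatl(L), r);
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    negll += 0.5 * (kk2 * LOG2PI + logdet + arma::dot(q, q));

    arma::mat Linv = arma::inv(arma::trimatl(L));
    arma::mat P = Linv.t() * Linv;       // S^-1
    arma::vec qq = Linv.t() * q;         // S^-1 r

    for (int j = 0; j < ncov; ++j) {
      const arma::mat& dM = dsig[g * ncov + j];
      // skip identically-zero derivatives cheaply
      if (dM(0, 0) == 0 && dM(1, 1) == 0 && dM(0, 1) == 0 &&
          dM(2, 2) == 0 && dM(3, 3) == 0 && dM(0, 2) == 0 &&
          dM(1, 3) == 0 && dM(0, 1) == 0 && dM(1, 2) == 0 &&
          dM(0, 3) == 0 && dM(2, 3) == 0 && dM(1, 0) == 0) continue;
      arma::mat dS = dM.submat(obs, obs);
      double term = 0.5 * (arma::as_scalar(qq.t() * dS * qq) -
                           arma::trace(P * dS));
      grad(j) -= term;  // gradient of negative ll
    }
    for (arma::uword j = 0; j < pmu; ++j) {
      double acc = 0.0;
      for (arma::uword m = 0; m < kk2; ++m)
        acc += D(i, obs(m), j) * qq(m);
      grad(ncov + j) -= acc;
    }
  }

  return List::create(_["value"] = negll,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}
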