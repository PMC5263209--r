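// Restricted log-likelihood for the founder-effect mixed model
//
//   y = X b + sum_j Z_j u_j + e,   u_j ~ N(0, s2_j I),  e_i ~ N(0, se2_{k(i)})
//
// Z_j are founder-probability column blocks (one block per QTL/cofactor
// term), residual variances are cross-specific. V = D + U Lambda U' with
// diagonal D and Lambda, so V^{-1} and log|V| use the Woodbury identity:
// only q x q factorizations are needed (q = total random columns).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// logpar: log variances, n_terms term variances then n_cross residuals.
// term: 0-based term index per column of U; cross: 0-based per observation.
// components=false returns only the negative restricted log-likelihood.
// [[Rcpp::export]]
Rcpp::List reml_eval_cpp(const arma::vec& logpar, const arma::vec& y,
                         const arma::mat& X, const arma::mat& U,
                         const arma::uvec& term, const arma::uvec& cross,
                         const int n_terms, const int n_cross,
                         const bool components)
{
  const uword n = y.n_elem;
  const uword q = U.n_cols;
  vec s2(std::max(n_terms, 1)), se2(n_cross);
  for (int j = 0; j < n_terms; j++) s2[j] = std::exp(logpar[j]);
  for (int k = 0; k < n_cross; k++) se2[k] = std::exp(logpar[n_terms + k]);
  vec d(n);
  for (uword i = 0; i < n; i++) d[i] = se2[cross[i]];
  vec dinv = 1.0 / d;
  double logdetV = accu(log(d));

  mat W, cholM;
  vec lam(q);
  if (q > 0) {
    for (uword c = 0; c < q; c++) lam[c] = s2[term[c]];
    W = U.each_col() % dinv;
    mat M = U.t() * W;
    for (uword c = 0; c < q; c++) M(c, c) += 1.0 / lam[c];
    if (!chol(cholM, M))
      return Rcpp::List::create(Rcpp::Named("nll") = 1e10);
    logdetV += 2.0 * accu(log(cholM.diag())) + accu(log(lam));
  }

  // V^{-1} A = D^{-1} A - W M^{-1} W' A
  auto vinv = [&](const mat& A) -> mat {
    mat R = A.each_col() % dinv;
    if (q > 0) {
      mat t = solve(trimatu(cholM),
                    solve(trimatl(cholM.t()), W.t() * A));
      R -= W * t;
    }
    return R;
  };

  mat VinvX = vinv(X);
  mat A = X.t() * VinvX;
  mat cholA;
  if (!chol(cholA, A))
    return Rcpp::List::create(Rcpp::Named("nll") = 1e10);
  double logdetA = 2.0 * accu(log(cholA.diag()));
  vec Vinvy = vinv(mat(y));
  vec Xty = X.t() * Vinvy;
  vec b = solve(trimatu(cholA), solve(trimatl(cholA.t()), Xty));
  double yPy = dot(y, Vinvy) - dot(Xty, b);
  double nll = 0.5 * (logdetV + logdetA + yPy);
  if (!components)
    return Rcpp::List::create(Rcpp::Named("nll") = nll);

  vec Py = Vinvy - VinvX * b;
  mat Ainv = inv_sympd(A);
  vec u;
  mat pev;
  if (q > 0) {
    u = lam % (U.t() * Py);
    mat UtVinvU = U.t() * vinv(U);
    mat UtVinvX = U.t() * VinvX;
    mat UtPU = UtVinvU - UtVinvX * Ainv * UtVinvX.t();
    pev = diagmat(lam) - diagmat(lam) * UtPU * diagmat(lam);
  }
  return Rcpp::List::create(
    Rcpp::Named("nll") = nll,
    Rcpp::Named("beta") = b,
    Rcpp::Named("beta_cov") = Ainv,
    Rcpp::Named("blup") = u,
    Rcpp::Named("pev") = pev,
    Rcpp::Named("s2_terms") = s2.head(std::max(n_terms, 0)),
    Rcpp::Named("s2_resid") = se2,
    Rcpp::Named("yPy") = yPy);
}
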