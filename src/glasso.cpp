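// Graphical lasso via block coordinate descent (Friedman-style):
// each column's sub-problem is an L1-penalized regression solved by
// coordinate descent with soft thresholding. The diagonal is not penalized
// (W keeps the input diagonal), matching the convention used for
// regularized partial-correlation networks. Accepts a full penalty matrix
// so constrained refits (zero penalty on a fixed support) reuse the same
// solver, and optional warm starts for path estimation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_mat_cpp(const arma::mat& S, const arma::mat& Rho,
                          double tol = 1e-4, int maxit = 200,
                          Rcpp::Nullable<Rcpp::NumericMatrix> W0 = R_NilValue,
                          Rcpp::Nullable<Rcpp::NumericMatrix> B0 = R_NilValue) {
  const int p = S.n_rows;
  mat W = S;                 // working covariance estimate
  mat B(p, p, fill::zeros);  // regression coefficients, column j excludes j
  if (W0.isNotNull()) W = Rcpp::as<mat>(W0.get());
  if (B0.isNotNull()) B = Rcpp::as<mat>(B0.get());
  W.diag() = S.diag();       // diagonal unpenalized: always the input's

  double offmean = 0.0;
  int cnt = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { offmean += std::fabs(S(i, j)); ++cnt; }
  offmean = (cnt > 0) ? offmean / cnt : 0.0;
  const double thr = tol * std::max(offmean, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < maxit; ++iter) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec rho12 = Rho.col(j); rho12 = rho12.elem(idx);
      vec b = B.col(j); b = b.elem(idx);
      // inner lasso coordinate descent
      for (int it2 = 0; it2 < 200; ++it2) {
        double max_db = 0.0;
        for (int i = 0; i < p - 1; ++i) {
          double r = s12(i) - dot(W11.col(i), b) + W11(i, i) * b(i);
          double bnew = soft(r, rho12(i)) / W11(i, i);
          double db = std::fabs(bnew - b(i));
          if (db > max_db) max_db = db;
          b(i) = bnew;
        }
        if (max_db < 0.1 * thr + 1e-12) break;
      }
      vec w12 = W11 * b;
      for (int i = 0, k = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::fabs(W(i, j) - w12(k));
        if (d > max_delta) max_delta = d;
        W(i, j) = w12(k);
        W(j, i) = w12(k);
        B(i, j) = b(k);
        ++k;
      }
    }
    if (max_delta < thr) { converged = true; break; }
  }

  // recover the precision matrix from (W, B)
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned) j);
    vec b = B.col(j); b = b.elem(idx);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = t22;
    for (int i = 0, k = 0; i < p; ++i) {
      if (i == j) continue;
      Theta(i, j) += -b(k) * t22 / 2.0;  // averaged with the (j,i) pass
      Theta(j, i) += -b(k) * t22 / 2.0;
      ++k;
    }
  }

  // standardized negative precision off-diagonals = partial correlations
  mat P(p, p, fill::zeros);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j)
        P(i, j) = -Theta(i, j) / std::sqrt(Theta(i, i) * Theta(j, j));
  P = (P + P.t()) / 2.0;
  P.diag().zeros();

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("partials") = P,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("iterations") = iter + 1,
                            Rcpp::Named("converged") = converged);
}

// Scalar-penalty convenience wrapper.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      double tol = 1e-4, int maxit = 200,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W0 = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B0 = R_NilValue) {
  arma::mat Rho(S.n_rows, S.n_cols);
  Rho.fill(rho);
  return glasso_mat_cpp(S, Rho, tol, maxit, W0, B0);
}
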