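#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Evaluate a template set: polarity-invariant assignment (argmax squared
// projection) and the explained sum of squares.
static double evaluate(const arma::mat& X, const arma::mat& T,
                       arma::uvec& L) {
  arma::mat A = X * T;            // n x k projections
  arma::mat A2 = A % A;
  double expl = 0.0;
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::uword j;
    double m = A2.row(i).max(j);
    L(i) = j;
    expl += m;
  }
  return expl;
}

// Dominant eigenvector of sum_{i in cluster} x_i x_i^T by power iteration,
// warm-started from the current template.
static arma::vec dominant_dir(const arma::mat& Xk, arma::vec t) {
  for (int p = 0; p < 100; ++p) {
    arma::vec t2 = Xk.t() * (Xk * t);
    double nt = arma::norm(t2);
    if (nt <= 0) break;
    t2 /= nt;
    double d = std::min(arma::norm(t2 - t), arma::norm(t2 + t));
    t = t2;
    if (d < 1e-12) break;
  }
  return t;
}

// Modified (polarity-invariant) spatial k-means.
// X: n x C matrix of mean-removed maps (rows). inits: restarts x k matrix of
// 1-based row indices used as initial templates. Returns the best restart.
// [[Rcpp::export]]
List ms_kmeans_core(const arma::mat& X, const int k, const arma::imat& inits,
                    const int max_iter, const double tol) {
  const arma::uword n = X.n_rows, C = X.n_cols;
  if ((arma::uword)k > n) stop("k exceeds the number of maps");
  const double ssq = arma::accu(X % X);
  if (ssq <= 0) stop("all maps are zero");

  arma::mat bestT;
  double bestExpl = -1.0;

  for (arma::uword r = 0; r < inits.n_rows; ++r) {
    arma::mat T(C, k);
    for (int j = 0; j < k; ++j) {
      arma::rowvec v = X.row(inits(r, j) - 1);
      double nv = arma::norm(v, 2);
      if (nv <= 0) { v.zeros(); v(j % C) = 1.0; nv = 1.0; }
      T.col(j) = (v / nv).t();
    }
    arma::uvec L(n, arma::fill::zeros);
    double prev = -1.0;
    for (int it = 0; it < max_iter; ++it) {
      double expl = evaluate(X, T, L);
      if (prev >= 0 &&
          std::fabs(expl - prev) < tol * std::max(prev, 1e-300)) break;
      prev = expl;
      for (int j = 0; j < k; ++j) {
        arma::uvec idx = arma::find(L == (arma::uword)j);
        if (idx.is_empty()) {
          // re-seed an empty cluster with the worst-fitted map
          arma::mat A = X * T;
          arma::vec fit = arma::max(A % A, 1);
          arma::uword wi = fit.index_min();
          arma::rowvec v = X.row(wi);
          double nv = arma::norm(v, 2);
          if (nv > 0) T.col(j) = (v / nv).t();
          continue;
        }
        T.col(j) = dominant_dir(X.rows(idx), T.col(j));
      }
    }
    arma::uvec Lf(n);
    double expl = evaluate(X, T, Lf);
    if (expl > bestExpl) {
      bestExpl = expl;
      bestT = T;
    }
  }

  arma::uvec L(n);
  double expl = evaluate(X, bestT, L);
  double sigma2 = (ssq - expl) / (double)(n * (C - 1));
  return List::create(_["templates"] = bestT,
                      _["assignments"] = L + 1,
                      _["ev"] = expl / ssq,
                      _["sigma2"] = sigma2);
}
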