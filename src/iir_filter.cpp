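#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// direct-form II transposed IIR filter, zero initial conditions
static void filt_inplace(const arma::vec& b, const arma::vec& a,
                         arma::vec& x) {
  const arma::uword nb = b.n_elem, na = a.n_elem;
  const arma::uword nz = std::max(nb, na) - 1;
  arma::vec z(nz, arma::fill::zeros);
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double xi = x(i);
    double yi = b(0) * xi + (nz ? z(0) : 0.0);
    for (arma::uword j = 1; j <= nz; ++j) {
      double zj = (j < nz) ? z(j) : 0.0;
      z(j - 1) = zj + (j < nb ? b(j) * xi : 0.0) -
                 (j < na ? a(j) * yi : 0.0);
    }
    x(i) = yi;
  }
}

// two-pass (forward + backward) filtering of each column of X, with
// reflect padding of np samples at both ends per signal
// [[Rcpp::export]]
arma::mat iir_filtfilt_mat(const arma::vec& b, const arma::vec& a,
                           const arma::mat& X, const int np) {
  const arma::uword n = X.n_rows;
  arma::mat out(n, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    arma::vec x = X.col(c);
    arma::vec y(n + 2 * np);
    for (int i = 0; i < np; ++i) y(i) = 2 * x(0) - x(np - i);
    y.subvec(np, np + n - 1) = x;
    for (int i = 0; i < np; ++i) y(np + n + i) = 2 * x(n - 1) - x(n - 2 - i);
    filt_inplace(b, a, y);
    y = arma::reverse(y);
    filt_inplace(b, a, y);
    y = arma::reverse(y);
    out.col(c) = y.subvec(np, np + n - 1);
  }
  return out;
}
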