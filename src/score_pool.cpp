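#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Residual sums of squares for a pool of candidate fragments, one medium.
//
// Each row k packs the normal-equation pieces of the least-squares order
// tensor problem for candidate k: Mk (K x 15) the upper triangle of
// A'A (row-major order (1,1),(1,2)..(1,5),(2,2)..(5,5)), Bk (K x 5) = A'd,
// dd (K) = |d|^2. The minimum-norm least-squares solution is taken through
// an eigendecomposition with relative cutoff `rcond` on the singular-value
// scale (i.e. eigenvalues below rcond^2 * max are dropped), matching the
// package's svd-based pseudo-inverse fit. Returns |A s - d|^2 per row.
// [[Rcpp::export]]
arma::vec scorePoolCpp(const arma::mat& Mk, const arma::mat& Bk,
                       const arma::vec& dd, double rcond) {
  const arma::uword K = Mk.n_rows;
  arma::vec out(K);
  arma::mat M(5, 5), V;
  arma::vec b(5), ev, s(5);
  for (arma::uword k = 0; k < K; ++k) {
    arma::uword p = 0;
    for (arma::uword i = 0; i < 5; ++i)
      for (arma::uword j = i; j < 5; ++j, ++p) {
        M(i, j) = Mk(k, p);
        M(j, i) = Mk(k, p);
      }
    b = Bk.row(k).t();
    if (!arma::eig_sym(ev, V, M)) {
      out(k) = dd(k);
      continue;
    }
    const double cut = rcond * rcond * ev.max();
    s.zeros();
    for (arma::uword i = 0; i < 5; ++i)
      if (ev(i) > cut && ev(i) > 0.0)
        s += (arma::dot(V.col(i), b) / ev(i)) * V.col(i);
    const double ss = dd(k) - 2.0 * arma::dot(b, s) + arma::dot(s, M * s);
    out(k) = ss > 0.0 ? ss : 0.0;
  }
  return out;
}

// Minimum-norm least-squares tensor solutions for a pool, same packing
// and cutoff as scorePoolCpp; returns the K x 5 solution matrix so the
// caller can evaluate residuals exactly (avoiding the cancellation of
// the normal-equation identity near zero residual).
// [[Rcpp::export]]
arma::mat solvePoolCpp(const arma::mat& Mk, const arma::mat& Bk,
                       double rcond) {
  const arma::uword K = Mk.n_rows;
  arma::mat out(K, 5);
  arma::mat M(5, 5), V;
  arma::vec b(5), ev, s(5);
  for (arma::uword k = 0; k < K; ++k) {
    arma::uword p = 0;
    for (arma::uword i = 0; i < 5; ++i)
      for (arma::uword j = i; j < 5; ++j, ++p) {
        M(i, j) = Mk(k, p);
        M(j, i) = Mk(k, p);
      }
    b = Bk.row(k).t();
    s.zeros();
    if (arma::eig_sym(ev, V, M)) {
      const double cut = rcond * rcond * ev.max();
      for (arma::uword i = 0; i < 5; ++i)
        if (ev(i) > cut && ev(i) > 0.0)
          s += (arma::dot(V.col(i), b) / ev(i)) * V.col(i);
    }
    out.row(k) = s.t();
  }
  return out;
}
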