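// Iteratively reweighted least squares core for sparse real-spectrum
// reconstruction (virtual-echo model).
//
// Solves, per right-hand-side column b, the weighted minimum-norm problem
//   s = D A' (A D A' + reg I)^{-1} b ,   D = diag(1/w),
// iterating w_j = (s_j^2 + eps)^{(p-2)/2} with eps decayed geometrically,
// which drives s toward an lp-sparse solution consistent with the sampled
// rows. When the row count reaches the number of unknowns the system is
// determined and the weights are irrelevant: a single least-squares solve is
// used for all columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".irls_core_cpp")]]
arma::mat irls_core_cpp(const arma::mat& A, const arma::mat& B, double p,
                        int n_iter, double reg) {
  const int r = A.n_rows, M = A.n_cols, nc = B.n_cols;
  mat S(M, nc);

  if (r >= M) {
    mat G = A.t() * A;
    G.diag() += reg * trace(G) / M;
    S = solve(G, A.t() * B, solve_opts::likely_sympd);
    return S;
  }

  for (int c = 0; c < nc; ++c) {
    const vec b = B.col(c);
    vec D(M, fill::ones), s(M, fill::zeros);
    double decay = 1.0;
    for (int it = 0; it < n_iter; ++it) {
      mat K = A * diagmat(D) * A.t();
      K.diag() += reg * (trace(K) / r + 1e-300);
      vec z = solve(K, b, solve_opts::likely_sympd);
      s = D % (A.t() * z);
      const double m2 = dot(s, s) > 0 ? max(square(s)) : 1.0;
      decay *= 0.5;
      const double eps = m2 * 0.1 * decay + 1e-12 * m2;
      vec w = pow(square(s) + eps, (p - 2.0) / 2.0);
      w /= w.max();
      D = 1.0 / w;
    }
    S.col(c) = s;
  }
  return S;
}
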