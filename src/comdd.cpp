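// Masked alternating least squares for co-processed multi-dimensional
// decomposition (co-MDD).
//
// The model for the nu-th plane is  S^nu = sum_i alpha_i^nu  a_i (x) b_i (x) c_i
// with shape vectors shared across planes and only the per-plane amplitudes
// alpha varying. The direct dimension is Fourier transformed beforehand, so
// the data enter as a real matrix X (F x m) whose m columns are the observed
// (indirect..., plane) cells; `obs` gives, per column, the 0-based index along
// each indirect (hypercomplex-expanded) axis and the plane index.
//
// Each sub-step solves a Tikhonov-regularised least-squares problem restricted
// to the sampled cells (penalty lambda * ||x||^2). After every sweep the shape
// vectors are renormalised to unit norm with norms (and signs, fixed so the
// max-|element| is positive) absorbed into the amplitudes. Iterations stop at
// n_iter or when the relative residual change falls below tol.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".comdd_als_cpp")]]
Rcpp::List comdd_als_cpp(const arma::mat& X, const arma::imat& obs,
                         Rcpp::List factors0, arma::mat amp, double lambda,
                         int n_iter, double tol) {
  const int m = X.n_cols;
  const int K = obs.n_cols - 1;  // number of indirect axes
  const int R = amp.n_cols;
  const int P = amp.n_rows;

  std::vector<mat> F(K);
  for (int k = 0; k < K; ++k) F[k] = Rcpp::as<mat>(factors0[k + 1]);
  mat A = Rcpp::as<mat>(factors0[0]);

  // observation lists grouped by row of each indirect axis and by plane
  std::vector<std::vector<std::vector<int>>> grp(K);
  for (int k = 0; k < K; ++k) {
    grp[k].assign(F[k].n_rows, {});
    for (int j = 0; j < m; ++j) grp[k][obs(j, k)].push_back(j);
  }
  std::vector<std::vector<int>> grpP(P);
  for (int j = 0; j < m; ++j) grpP[obs(j, K)].push_back(j);

  const double normX = norm(X, "fro");
  double relres_prev = datum::inf;
  std::vector<double> res_trace;
  int sweeps = 0;

  // previous-sweep factors for the line-search extrapolation that crosses
  // the slow 'swamp' regimes of collinear-component ALS
  mat A_prev = A, amp_prev = amp;
  std::vector<mat> F_prev = F;

  auto resid_of = [&](const mat& Ax, const std::vector<mat>& Fx,
                      const mat& ampx, mat& Wbuf) {
    for (int j = 0; j < m; ++j) {
      rowvec w = ampx.row(obs(j, K));
      for (int k = 0; k < K; ++k) w %= Fx[k].row(obs(j, k));
      Wbuf.row(j) = w;
    }
    return norm(X - Ax * Wbuf.t(), "fro") / (normX > 0 ? normX : 1.0);
  };

  mat W(m, R), Wk(m, R);
  // ridge scaled to each sub-problem's normal matrix: keeps every solve well
  // conditioned and damps degenerate component growth at any data scale
  auto ridge = [&](mat& G) { G.diag() += lambda * trace(G) / G.n_rows + 1e-300; };

  for (int it = 0; it < n_iter; ++it) {
    // W(j,i) = prod_k F_k(obs_jk, i) * amp(plane_j, i)
    for (int j = 0; j < m; ++j) {
      rowvec w = amp.row(obs(j, K));
      for (int k = 0; k < K; ++k) w %= F[k].row(obs(j, k));
      W.row(j) = w;
    }
    // direct-dimension shapes: one dense ridge problem (mask is f-independent)
    mat G = W.t() * W;
    ridge(G);
    A = solve(G, W.t() * X.t(), solve_opts::likely_sympd).t();

    mat AtA = A.t() * A;
    mat C = A.t() * X;  // R x m

    // indirect shape updates, one axis at a time
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < m; ++j) {
        rowvec w = amp.row(obs(j, K));
        for (int k2 = 0; k2 < K; ++k2)
          if (k2 != k) w %= F[k2].row(obs(j, k2));
        Wk.row(j) = w;
      }
      for (size_t t = 0; t < grp[k].size(); ++t) {
        const std::vector<int>& js = grp[k][t];
        if (js.empty()) { F[k].row(t).zeros(); continue; }
        mat S(R, R, fill::zeros);
        vec h(R, fill::zeros);
        for (int j : js) {
          const rowvec w = Wk.row(j);
          S += w.t() * w;
          h += (C.col(j) % w.t());
        }
        mat Gt = AtA % S;
        ridge(Gt);
        F[k].row(t) = solve(Gt, h, solve_opts::likely_sympd).t();
      }
    }

    // per-plane amplitudes
    for (int j = 0; j < m; ++j) {
      rowvec w = F[0].row(obs(j, 0));
      for (int k = 1; k < K; ++k) w %= F[k].row(obs(j, k));
      Wk.row(j) = w;
    }
    for (int p = 0; p < P; ++p) {
      const std::vector<int>& js = grpP[p];
      if (js.empty()) { amp.row(p).zeros(); continue; }
      mat S(R, R, fill::zeros);
      vec h(R, fill::zeros);
      for (int j : js) {
        const rowvec w = Wk.row(j);
        S += w.t() * w;
        h += (C.col(j) % w.t());
      }
      mat Gp = AtA % S;
      ridge(Gp);
      amp.row(p) = solve(Gp, h, solve_opts::likely_sympd).t();
    }

    // renormalise shapes, absorb norm and sign into amplitudes
    for (int i = 0; i < R; ++i) {
      double nrm = norm(A.col(i));
      if (nrm > 0) {
        uword imax = index_max(abs(A.col(i)));
        double sgn = A(imax, i) < 0 ? -1.0 : 1.0;
        A.col(i) /= (nrm * sgn);
        amp.col(i) *= (nrm * sgn);
      }
      for (int k = 0; k < K; ++k) {
        double nk = norm(F[k].col(i));
        if (nk > 0) {
          uword imax = index_max(abs(F[k].col(i)));
          double sgn = F[k](imax, i) < 0 ? -1.0 : 1.0;
          F[k].col(i) /= (nk * sgn);
          amp.col(i) *= (nk * sgn);
        }
      }
    }

    // residual on the observed cells
    double relres = resid_of(A, F, amp, W);

    // line-search extrapolation along the last sweep's direction
    if (it >= 2) {
      const double beta = std::cbrt((double)it) - 1.0;
      mat A_e = A + beta * (A - A_prev);
      mat amp_e = amp + beta * (amp - amp_prev);
      std::vector<mat> F_e(K);
      for (int k = 0; k < K; ++k) F_e[k] = F[k] + beta * (F[k] - F_prev[k]);
      double rel_e = resid_of(A_e, F_e, amp_e, Wk);
      if (rel_e < relres) {
        A_prev = A; amp_prev = amp; F_prev = F;
        A = A_e; amp = amp_e; F = F_e;
        relres = rel_e;
      } else {
        A_prev = A; amp_prev = amp; F_prev = F;
      }
    } else {
      A_prev = A; amp_prev = amp; F_prev = F;
    }

    res_trace.push_back(relres);
    sweeps = it + 1;
    if (std::abs(relres_prev - relres) < tol * std::max(1.0, relres)) break;
    relres_prev = relres;
  }

  Rcpp::List Fout(K + 1);
  Fout[0] = A;
  for (int k = 0; k < K; ++k) Fout[k + 1] = F[k];
  return Rcpp::List::create(Rcpp::Named("factors") = Fout,
                            Rcpp::Named("amplitudes") = amp,
                            Rcpp::Named("n_sweeps") = sweeps,
                            Rcpp::Named("residual_trace") = res_trace);
}
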