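// Graphical lasso: blockwise coordinate descent (Friedman, Hastie &
// Tibshirani 2008) with elementwise penalties, run over a decreasing
// penalty path with warm starts. The elementwise form also yields the
// pattern-constrained Gaussian MLE (zero penalty on allowed edges, an
// effectively infinite penalty on forbidden ones) used for EBIC refits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Row lasso: minimise 0.5 b'Vb - u'b + sum_k rho_k |b_k| by coordinate
// descent. V must have a strictly positive diagonal.
static void lasso_cd(const mat& V, const vec& u, const vec& rho, vec& b,
                     int maxit, double tol) {
  const uword m = u.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < m; ++k) {
      double grad = u(k) - dot(V.col(k), b) + V(k, k) * b(k);
      double bnew = soft(grad, rho(k)) / V(k, k);
      double d = std::abs(bnew - b(k));
      if (d > dmax) dmax = d;
      b(k) = bnew;
    }
    if (dmax < tol) break;
  }
}

// One glasso fit with penalty matrix Rho, starting from (and overwriting)
// the working covariance W and the p x (p-1) beta warm starts B.
static void glasso_fit(const mat& S, const mat& Rho, mat& W, mat& B,
                       mat& Theta, int maxit, double tol) {
  const uword p = S.n_rows;
  W.diag() = S.diag() + Rho.diag();
  double sbar = mean(mean(abs(S - diagmat(S.diag())))) + 1e-12;
  double thr = tol * sbar;

  uvec all = regspace<uvec>(0, p - 1);
  for (int outer = 0; outer < maxit; ++outer) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec r12 = Rho.col(j); r12 = r12.elem(idx);
      vec b = B.col(j);
      lasso_cd(W11, s12, r12, b, 200, thr * 0.1 + 1e-10);
      B.col(j) = b;
      vec w12 = W11 * b;
      for (uword k = 0; k < idx.n_elem; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (dmax < thr) break;
  }

  // Recover the precision matrix from the final betas.
  Theta.zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = B.col(j);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = t22;
    for (uword k = 0; k < idx.n_elem; ++k)
      Theta(idx(k), j) = -b(k) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  // soft-thresholding leaves exact zeros in the betas; enforce exact zeros
  // in Theta where both directional betas vanished
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    for (uword k = 0; k < idx.n_elem; ++k) {
      uword i = idx(k);
      if (i < j) continue;
      uword pos_j = (j < i) ? j : j - 1;   // position of j within idx of i
      bool zero_ij = (B(k, j) == 0.0);
      bool zero_ji = (B(pos_j, i) == 0.0);
      if (zero_ij && zero_ji) { Theta(i, j) = 0.0; Theta(j, i) = 0.0; }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& rho_path,
                           int maxit = 100, double tol = 1e-4) {
  const uword p = S.n_rows;
  const uword L = rho_path.n_elem;
  mat W = S; W.diag() += rho_path(0);
  mat B(p - 1, p, fill::zeros);
  mat Theta(p, p, fill::zeros);
  mat Rho(p, p);

  Rcpp::List thetas(L);
  vec loglik(L), nedges(L);
  for (uword l = 0; l < L; ++l) {
    Rho.fill(rho_path(l));
    glasso_fit(S, Rho, W, B, Theta, maxit, tol);
    thetas[l] = Theta;
    double ld, sign;
    log_det(ld, sign, Theta);
    loglik(l) = 0.5 * (ld - trace(S * Theta));   // per observation; x n in R
    mat off = Theta; off.diag().zeros();
    nedges(l) = accu(off != 0) / 2.0;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("loglik_unit") = loglik,
                            Rcpp::Named("n_edges") = nedges);
}

//' @noRd
// [[Rcpp::export(name = ".glasso_refit_cpp")]]
Rcpp::List glasso_refit_cpp(const arma::mat& S, const arma::umat& adj,
                            int maxit = 200, double tol = 1e-6) {
  const uword p = S.n_rows;
  mat Rho(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j && adj(i, j) == 0) Rho(i, j) = 1e6;
  mat W = S;
  mat B(p - 1, p, fill::zeros);
  mat Theta(p, p, fill::zeros);
  glasso_fit(S, Rho, W, B, Theta, maxit, tol);
  double ld, sign;
  log_det(ld, sign, Theta);
  double ll = 0.5 * (ld - trace(S * Theta));
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("loglik_unit") = ll);
}
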