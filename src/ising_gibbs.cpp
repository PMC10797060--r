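// Single-chain Gibbs sampler for a 0/1 Ising model with couplings W and
// per-node fields h: P(x_i = 1 | rest) = plogis(h_i + sum_j w_ij x_j).
// Uses R's RNG stream so draws are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

//' @noRd
// [[Rcpp::export(name = ".ising_gibbs_cpp")]]
arma::imat ising_gibbs_cpp(const arma::mat& W, const arma::vec& h,
                           int n, int burn_in, int thin) {
  const uword p = W.n_rows;
  imat out(n, p);
  vec x(p);
  for (uword j = 0; j < p; ++j) x(j) = (R::unif_rand() < 0.5) ? 1.0 : 0.0;

  long total = (long)burn_in + (long)n * thin;
  int kept = 0;
  for (long sweep = 0; sweep < total; ++sweep) {
    for (uword j = 0; j < p; ++j) {
      double eta = h(j) + dot(W.col(j), x);
      double pj = 1.0 / (1.0 + std::exp(-eta));
      x(j) = (R::unif_rand() < pj) ? 1.0 : 0.0;
    }
    if (sweep >= burn_in && ((sweep - burn_in + 1) % thin == 0)) {
      for (uword j = 0; j < p; ++j) out(kept, j) = (int)x(j);
      ++kept;
      if (kept == n) break;
    }
  }
  return out;
}
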