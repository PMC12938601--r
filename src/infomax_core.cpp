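// Natural-gradient Infomax inner loop (logistic nonlinearity) on
// pre-sphered data. Block order is drawn from R's RNG so results are
// reproducible under set.seed() like the rest of the package.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(.infomax_core)]]
List infomax_core(const arma::mat& Xw, int max_iter, double lrate,
                  double tol, int block, int anneal_after, double anneal) {
  const arma::uword nc = Xw.n_rows;
  const arma::uword n = Xw.n_cols;
  const arma::uword nb = n / block;

  arma::mat W = arma::eye(nc, nc);
  arma::mat I = arma::eye(nc, nc);
  arma::mat prev_dW;
  bool have_prev = false;
  double lr = lrate;
  bool converged = false;
  int it = 0;
  const double cos60 = 0.5;

  while (it < max_iter) {
    ++it;
    arma::mat W_old = W;
    IntegerVector perm = sample(static_cast<int>(n), static_cast<int>(n),
                                false);
    bool blown = false;
    for (arma::uword b = 0; b < nb; ++b) {
      arma::uvec idx(block);
      for (int j = 0; j < block; ++j)
        idx[j] = static_cast<arma::uword>(perm[b * block + j] - 1);
      arma::mat u = W * Xw.cols(idx);
      arma::mat y = 1.0 / (1.0 + arma::exp(-u));
      W += lr * (I + (1.0 - 2.0 * y) * u.t() / block) * W;
      if (!W.is_finite() || arma::abs(W).max() > 1e8) { blown = true; break; }
    }
    if (blown) {
      lr /= 2.0;
      W = arma::eye(nc, nc);
      have_prev = false;
      continue;
    }
    arma::mat dW = W - W_old;
    if (have_prev) {
      double num = arma::accu(dW % prev_dW);
      double den = std::sqrt(arma::accu(dW % dW) *
                             arma::accu(prev_dW % prev_dW));
      if (den > 0 && num / den < cos60) lr *= 0.9;
    }
    if (it > anneal_after) lr *= anneal;
    prev_dW = dW;
    have_prev = true;
    if (std::sqrt(arma::accu(dW % dW) / (nc * nc)) < tol) {
      converged = true;
      break;
    }
  }
  return List::create(Named("W") = W, Named("iterations") = it,
                      Named("converged") = converged);
}
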