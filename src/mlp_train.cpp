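// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "fast_tanh.h"
using namespace Rcpp;

// One Adam epoch of the pointwise tanh network under the Huber loss.
// `params`, `adam_m`, `adam_v` are lists of matrices/vectors ordered
// W1, b1, ..., WL, bL; they are modified in place (the R caller owns fresh
// copies). `order` is the 1-based shuffled row order for minibatching.
// Returns the mean Huber training loss of the epoch.
// [[Rcpp::export]]
double mlp_adam_epoch_cpp(List params, List adam_m, List adam_v,
                          IntegerVector step_counter, const arma::mat &X,
                          const arma::vec &y, const arma::uvec &order,
                          int batch_size, double lr, bool huber_literal,
                          double beta1 = 0.9, double beta2 = 0.999,
                          double eps = 1e-8) {
  const int n_par = params.size();
  const int L = n_par / 2;
  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(params[2 * l]);
    b[l] = as<arma::rowvec>(params[2 * l + 1]);
    mW[l] = as<arma::mat>(adam_m[2 * l]);
    mb[l] = as<arma::rowvec>(adam_m[2 * l + 1]);
    vW[l] = as<arma::mat>(adam_v[2 * l]);
    vb[l] = as<arma::rowvec>(adam_v[2 * l + 1]);
  }
  int t = step_counter[0];
  const arma::uword n = X.n_rows;
  double total = 0.0;

  std::vector<arma::mat> H(L); // activations per hidden layer
  for (arma::uword start = 0; start < n; start += batch_size) {
    arma::uword stop = std::min<arma::uword>(start + batch_size, n) - 1;
    arma::uvec idx = order.subvec(start, stop) - 1;
    arma::mat Xb = X.rows(idx);
    arma::vec yb = y(idx);
    const arma::uword B = Xb.n_rows;

    // forward
    arma::mat h = Xb;
    for (int l = 0; l < L - 1; ++l) {
      h = h * W[l];
      h.each_row() += b[l];
      lanssm_tanh_array(h.memptr(), h.n_elem);
      H[l] = h;
    }
    arma::vec yhat = h * W[L - 1].col(0) + b[L - 1][0];
    arma::vec d = yhat - yb;
    for (arma::uword i = 0; i < B; ++i) {
      double ad = std::fabs(d[i]);
      total += ad <= 1.0 ? 0.5 * ad * ad
                         : (huber_literal ? 0.5 + ad : ad - 0.5);
    }

    // backward (Huber gradient clamps the residual at +/- 1)
    arma::mat delta(B, 1);
    for (arma::uword i = 0; i < B; ++i)
      delta(i, 0) = (std::fabs(d[i]) <= 1.0 ? d[i]
                                            : (d[i] > 0 ? 1.0 : -1.0)) / B;
    ++t;
    double bc1 = 1.0 - std::pow(beta1, t);
    double bc2 = 1.0 - std::pow(beta2, t);
    for (int l = L - 1; l >= 0; --l) {
      const arma::mat &h_prev = (l == 0) ? Xb : H[l - 1];
      arma::mat gW = h_prev.t() * delta;
      arma::rowvec gb = arma::sum(delta, 0);
      if (l > 0) {
        delta = delta * W[l].t();
        delta %= (1.0 - arma::square(H[l - 1]));
      }
      mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
      vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
      W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
      mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
      vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
      b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
    }
  }
  for (int l = 0; l < L; ++l) {
    params[2 * l] = W[l];
    params[2 * l + 1] = b[l];
    adam_m[2 * l] = mW[l];
    adam_m[2 * l + 1] = mb[l];
    adam_v[2 * l] = vW[l];
    adam_v[2 * l + 1] = vb[l];
  }
  step_counter[0] = t;
  return total / n;
}
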