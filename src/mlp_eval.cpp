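// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "fast_tanh.h"
using namespace Rcpp;

// The hot loops of MCMC over a pointwise network spend most of their time
// in tanh; the shared vectorizable approximation (abs error < 3e-7)
// replaces the scalar libm call.
static void tanh_inplace(arma::mat &M) {
  lanssm_tanh_array(M.memptr(), M.n_elem);
}

// Batched dataset log-likelihood of a pointwise tanh network over a fixed
// dataset: for each (standardized) theta row, every trial's standardized
// (rt, choice) pair is pushed through the network and the scalar outputs
// are summed. The trial part of the first-layer pre-activation is shared
// across theta rows and computed once.
// [[Rcpp::export]]
arma::vec mlp_dataset_loglik_cpp(List Ws, List bs, const arma::mat &theta_s,
                                 const arma::mat &trial_s) {
  const int L = Ws.size();
  arma::mat W1 = as<arma::mat>(Ws[0]);
  arma::rowvec b1 = as<arma::rowvec>(bs[0]);
  const arma::uword d_theta = theta_s.n_cols;
  const arma::uword n_theta = theta_s.n_rows;
  const arma::uword n_trial = trial_s.n_rows;
  if (W1.n_rows != d_theta + trial_s.n_cols)
    stop("first-layer weight rows must equal theta dims + trial dims");

  arma::mat trial_pre =
      trial_s * W1.rows(d_theta, W1.n_rows - 1); // n_trial x h1
  trial_pre.each_row() += b1;
  arma::mat theta_pre = theta_s * W1.rows(0, d_theta - 1); // n_theta x h1

  // stack all (theta, trial) combinations into one activation matrix
  arma::mat H(n_theta * n_trial, W1.n_cols);
  for (arma::uword t = 0; t < n_theta; ++t) {
    arma::mat block = trial_pre;
    block.each_row() += theta_pre.row(t);
    H.rows(t * n_trial, (t + 1) * n_trial - 1) = block;
  }
  tanh_inplace(H);
  for (int l = 1; l < L - 1; ++l) {
    arma::mat W = as<arma::mat>(Ws[l]);
    arma::rowvec b = as<arma::rowvec>(bs[l]);
    H = H * W;
    H.each_row() += b;
    tanh_inplace(H);
  }
  arma::mat Wo = as<arma::mat>(Ws[L - 1]);
  double bo = as<arma::rowvec>(bs[L - 1])[0];
  arma::vec y = H * Wo.col(0) + bo;
  arma::vec out(n_theta);
  for (arma::uword t = 0; t < n_theta; ++t)
    out[t] = arma::accu(y.subvec(t * n_trial, (t + 1) * n_trial - 1));
  return out;
}

// Plain batched forward pass (vector of pointwise outputs for pre-built,
// standardized feature rows); shares the fast tanh with the kernel above.
// [[Rcpp::export]]
arma::vec mlp_forward_cpp(List Ws, List bs, const arma::mat &X) {
  const int L = Ws.size();
  arma::mat H = X;
  for (int l = 0; l < L - 1; ++l) {
    arma::mat W = as<arma::mat>(Ws[l]);
    arma::rowvec b = as<arma::rowvec>(bs[l]);
    H = H * W;
    H.each_row() += b;
    tanh_inplace(H);
  }
  arma::mat Wo = as<arma::mat>(Ws[L - 1]);
  double bo = as<arma::rowvec>(bs[L - 1])[0];
  return H * Wo.col(0) + bo;
}
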