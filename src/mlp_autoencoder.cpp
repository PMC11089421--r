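#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fully connected autoencoder trained with Adam on mean squared
// reconstruction error.  Hidden layers use ReLU; the bottleneck layer and
// the output layer are linear.  All randomness (initial weights, batch
// order) is supplied by the caller so training is reproducible from R's RNG.
//
// X            : N x E data matrix (rows are samples)
// W0, b0       : initial weights (list of E_prev x E_next matrices) / biases
// batch_order  : epochs x N matrix of 0-based sample indices
// linear_layers: 1-based indices of layers with linear activation
//                (bottleneck and output)
// [[Rcpp::export(name = ".mlp_ae_train_cpp")]]
Rcpp::List mlp_ae_train_cpp(const arma::mat& X, Rcpp::List W0, Rcpp::List b0,
                            const arma::imat& batch_order, int batch_size,
                            arma::ivec linear_layers,
                            double lr = 1e-3, double beta1 = 0.9,
                            double beta2 = 0.999, double eps = 1e-8) {
  const uword N = X.n_rows;
  const uword L = W0.size();
  const uword n_epochs = batch_order.n_rows;

  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  std::vector<bool> lin(L, false);
  for (uword l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<rowvec>(b0[l]);
    mW[l].zeros(size(W[l])); vW[l].zeros(size(W[l]));
    mb[l].zeros(size(b[l])); vb[l].zeros(size(b[l]));
  }
  for (uword i = 0; i < linear_layers.n_elem; ++i) {
    int li = linear_layers(i) - 1;
    if (li < 0 || li >= static_cast<int>(L)) Rcpp::stop("bad linear layer index");
    lin[li] = true;
  }

  std::vector<mat> A(L + 1), Z(L);
  long step = 0;
  double epoch_mse = NA_REAL;

  for (uword ep = 0; ep < n_epochs; ++ep) {
    double sse = 0.0; long nobs = 0;
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N) - 1;
      uvec idx(stop - start + 1);
      for (uword i = 0; i < idx.n_elem; ++i)
        idx(i) = static_cast<uword>(batch_order(ep, start + i));
      mat Xb = X.rows(idx);
      const double nb = static_cast<double>(Xb.n_rows);

      // forward
      A[0] = Xb;
      for (uword l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = lin[l] ? Z[l] : clamp(Z[l], 0.0, datum::inf);
      }

      mat diff = A[L] - Xb;
      if (!diff.is_finite()) Rcpp::stop("non-finite reconstruction loss");
      sse += accu(square(diff));
      nobs += Xb.n_elem;

      // backward (MSE over batch elements)
      mat delta = (2.0 / (nb * Xb.n_cols)) * diff;
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, static_cast<double>(step));
      const double bc2 = 1.0 - std::pow(beta2, static_cast<double>(step));
      for (int l = L - 1; l >= 0; --l) {
        if (!lin[l]) delta %= conv_to<mat>::from(Z[l] > 0.0);
        mat gW = A[l].t() * delta;
        rowvec gb = sum(delta, 0);
        if (l > 0) delta = delta * W[l].t();

        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * square(gW);
        W[l] -= lr * (mW[l] / bc1) / (sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * square(gb);
        b[l] -= lr * (mb[l] / bc1) / (sqrt(vb[l] / bc2) + eps);
      }
    }
    epoch_mse = sse / static_cast<double>(nobs);
  }

  Rcpp::List Wout(L), bout(L);
  for (uword l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return Rcpp::List::create(Rcpp::Named("weights") = Wout,
                            Rcpp::Named("biases") = bout,
                            Rcpp::Named("final_mse") = epoch_mse);
}
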