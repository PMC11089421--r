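#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Sparse inverse covariance by block coordinate descent (Friedman et al.).
// The diagonal of the precision matrix is not penalized; the working
// covariance starts at S + lambda I.  Returns both the regularized
// covariance W and the precision Theta.
// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-5, int maxit = 200) {
  const uword p = S.n_rows;
  if (S.n_cols != p) Rcpp::stop("S must be square");

  // diagonal unpenalized: the working covariance keeps diag(S)
  mat W = S;
  mat B(p - 1, p, fill::zeros);  // lasso coefficients, one column per node

  // mean absolute off-diagonal of S sets the convergence scale
  double s_off = 0.0;
  if (p > 1) {
    for (uword i = 0; i < p; ++i)
      for (uword j = 0; j < p; ++j)
        if (i != j) s_off += std::fabs(S(i, j));
    s_off /= static_cast<double>(p * (p - 1));
  }
  const double thr = tol * std::max(s_off, 1e-12);

  std::vector<uvec> rest(p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    rest[j] = idx;
  }

  for (int it = 0; it < maxit; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = rest[j];
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);

      // coordinate descent for 0.5 b'W11 b - s12'b + lambda ||b||_1
      for (int cd = 0; cd < 200; ++cd) {
        double cd_delta = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double grad = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
          double bnew = soft_threshold(grad, lambda) / W11(k, k);
          if (bnew != old) {
            beta(k) = bnew;
            cd_delta = std::max(cd_delta, std::fabs(bnew - old));
          }
        }
        if (cd_delta < thr) break;
      }
      B.col(j) = beta;

      vec w12 = W11 * beta;
      vec w_old = W.col(j);
      w_old = w_old(idx);
      max_delta = std::max(max_delta, abs(w12 - w_old).max());
      for (uword k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (max_delta < thr) break;
  }

  // recover the precision matrix from the final (W, B)
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const uvec& idx = rest[j];
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12(idx);
    double theta22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = theta22;
    for (uword k = 0; k < p - 1; ++k)
      Theta(idx(k), j) = -beta(k) * theta22;
  }
  Theta = 0.5 * (Theta + Theta.t());  // symmetrize coordinate-wise solutions

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = Theta);
}
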