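// 1D generative-neuron (Self-ONN) convolution kernels.
//
// A generative neuron computes y = b + sum_{k=1..q} w_k * (x^k), where x^k is
// the elementwise k-th power of the layer input and * is "same"-padded
// cross-correlation.  q = 1 reduces to an ordinary convolution layer.
//
// Layout contract (shared with the R side):
//   X   : cube [C, L, B]   (channels x length x batch)
//   W   : mat  [O, K*q*C]  column index = t*q*C + k*C + c  (0-based t, k, c)
//   b   : vec  [O]
//   Y   : cube [O, L, B]
// Zero "same" padding with pad = (K-1)/2, K odd.
//
// The kernel is evaluated tap by tap: with the elementwise powers stacked
// into Xpow [q*C, L+2*pad], each tap t contributes W_t [O, q*C] times a
// shifted window of Xpow.  This keeps all heavy work in GEMM calls without
// materializing the full im2col patch matrix (which would be K times larger
// than the input and dominates run time through sheer memory traffic).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void fill_powers(const mat& xs, int q, int pad, mat& xpow) {
  const int C = xs.n_rows, L = xs.n_cols;
  xpow.zeros();
  xpow.submat(0, pad, C - 1, pad + L - 1) = xs;
  for (int k = 1; k < q; ++k)
    xpow.rows(k * C, (k + 1) * C - 1) =
      xpow.rows((k - 1) * C, k * C - 1) % xpow.rows(0, C - 1);
}

// [[Rcpp::export]]
arma::cube selfonn_conv_fwd_cpp(const arma::cube& X, const arma::mat& W,
                                const arma::vec& b, int q, int K) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int O = W.n_rows, pad = (K - 1) / 2, qC = q * C;
  cube Y(O, L, B);
  mat xpow(qC, L + 2 * pad);
  for (int s = 0; s < B; ++s) {
    fill_powers(X.slice(s), q, pad, xpow);
    mat& Ys = Y.slice(s);
    Ys.zeros();
    for (int t = 0; t < K; ++t)
      Ys += W.cols(t * qC, (t + 1) * qC - 1) * xpow.cols(t, t + L - 1);
    Ys.each_col() += b;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List selfonn_conv_bwd_cpp(const arma::cube& X, const arma::mat& W,
                                const arma::cube& dY, int q, int K) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int O = W.n_rows, pad = (K - 1) / 2, qC = q * C;
  cube dX(C, L, B);
  mat dW(O, K * qC, fill::zeros);
  vec db(O, fill::zeros);
  mat xpow(qC, L + 2 * pad);
  mat dxpow(qC, L + 2 * pad);
  for (int s = 0; s < B; ++s) {
    fill_powers(X.slice(s), q, pad, xpow);
    const mat& dYs = dY.slice(s);
    db += sum(dYs, 1);
    dxpow.zeros();
    for (int t = 0; t < K; ++t) {
      dW.cols(t * qC, (t + 1) * qC - 1) +=
        dYs * xpow.cols(t, t + L - 1).t();
      dxpow.cols(t, t + L - 1) +=
        W.cols(t * qC, (t + 1) * qC - 1).t() * dYs;
    }
    // chain rule through the elementwise powers: d/dx x^(k+1) = (k+1) x^k
    mat& dXs = dX.slice(s);
    dXs = dxpow.submat(0, pad, C - 1, pad + L - 1);
    for (int k = 1; k < q; ++k)
      dXs += double(k + 1) *
        (xpow.submat((k - 1) * C, pad, k * C - 1, pad + L - 1) %
         dxpow.submat(k * C, pad, (k + 1) * C - 1, pad + L - 1));
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Direct-form-II-transposed IIR filter with initial conditions (a[0] = 1,
// b and a zero-padded to equal length, zi of length m-1).
// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem, m = b.n_elem;
  vec z(m, fill::zeros);
  z.head(m - 1) = zi;
  vec y(n);
  for (int i = 0; i < n; ++i) {
    const double yi = b[0] * x[i] + z[0];
    for (int j = 1; j < m; ++j)
      z[j - 1] = b[j] * x[i] + z[j] - a[j] * yi;
    y[i] = yi;
  }
  return y;
}

// Instance normalization over [C, L, B]: per channel, per sample statistics.
// [[Rcpp::export]]
Rcpp::List inorm_fwd_cpp(const arma::cube& X, const arma::vec& gamma,
                         const arma::vec& beta, double eps) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  cube Y(C, L, B), Xhat(C, L, B);
  mat istd(C, B);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    vec mu = mean(Xs, 1);
    mat Xc = Xs.each_col() - mu;
    vec v = mean(square(Xc), 1);
    vec is = 1.0 / sqrt(v + eps);
    istd.col(s) = is;
    Xhat.slice(s) = Xc.each_col() % is;
    Y.slice(s) = (Xhat.slice(s).each_col() % gamma);
    Y.slice(s).each_col() += beta;
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("xhat") = Xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List inorm_bwd_cpp(const arma::cube& dY, const arma::cube& Xhat,
                         const arma::mat& istd, const arma::vec& gamma) {
  const int C = dY.n_rows, L = dY.n_cols, B = dY.n_slices;
  cube dX(C, L, B);
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& dYs = dY.slice(s);
    const mat& Xh = Xhat.slice(s);
    dgamma += sum(dYs % Xh, 1);
    dbeta += sum(dYs, 1);
    mat dxhat = dYs.each_col() % gamma;
    vec s1 = sum(dxhat, 1) / L;
    vec s2 = sum(dxhat % Xh, 1) / L;
    mat tmp = dxhat.each_col() - s1;
    tmp -= Xh.each_col() % s2;
    dX.slice(s) = tmp.each_col() % istd.col(s);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Max pooling by 2 along the length axis; ties keep the left sample.
// [[Rcpp::export]]
Rcpp::List maxpool_fwd_cpp(const arma::cube& X) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  cube Y(C, L / 2, B), left(C, L / 2, B);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    for (int j = 0; j < L / 2; ++j) {
      const vec a = Xs.col(2 * j), b = Xs.col(2 * j + 1);
      const uvec m = (a >= b);
      Y.slice(s).col(j) = max(a, b);
      left.slice(s).col(j) = conv_to<vec>::from(m);
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("left") = left);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd_cpp(const arma::cube& dY, const arma::cube& left) {
  const int C = dY.n_rows, Lh = dY.n_cols, B = dY.n_slices;
  cube dX(C, 2 * Lh, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int j = 0; j < Lh; ++j) {
      const vec d = dY.slice(s).col(j);
      const vec m = left.slice(s).col(j);
      dX.slice(s).col(2 * j) = d % m;
      dX.slice(s).col(2 * j + 1) = d % (1.0 - m);
    }
  }
  return dX;
}

// Linear x2 upsampling: y[2i] = x[i], y[2i+1] = (x[i] + x[i+1])/2 with the
// trailing half-step clamped to the last sample (0-based).
// [[Rcpp::export]]
arma::cube upsample_fwd_cpp(const arma::cube& X) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  cube Y(C, 2 * L, B);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    mat& Ys = Y.slice(s);
    for (int j = 0; j < L - 1; ++j) {
      Ys.col(2 * j) = Xs.col(j);
      Ys.col(2 * j + 1) = 0.5 * (Xs.col(j) + Xs.col(j + 1));
    }
    Ys.col(2 * L - 2) = Xs.col(L - 1);
    Ys.col(2 * L - 1) = Xs.col(L - 1);
  }
  return Y;
}

// [[Rcpp::export]]
arma::cube upsample_bwd_cpp(const arma::cube& dY) {
  const int C = dY.n_rows, L2 = dY.n_cols, B = dY.n_slices;
  const int L = L2 / 2;
  cube dX(C, L, B);
  for (int s = 0; s < B; ++s) {
    const mat& d = dY.slice(s);
    mat& dXs = dX.slice(s);
    for (int j = 0; j < L; ++j) dXs.col(j) = d.col(2 * j);
    for (int j = 0; j < L - 1; ++j) {
      dXs.col(j) += 0.5 * d.col(2 * j + 1);
      dXs.col(j + 1) += 0.5 * d.col(2 * j + 1);
    }
    dXs.col(L - 1) += d.col(2 * L - 1);
  }
  return dX;
}
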