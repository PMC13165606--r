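// Temporal convolution kernels for the EEG model.
//
// Layout convention: signal batches are cubes (channels x time x batch),
// matching R arrays with dim c(C, T, B). All convolutions use odd kernel
// lengths and zero "same" padding, so the time axis is preserved. Channel
// rows are staged into contiguous buffers before the tap loops; the grouped
// convolutions go through im2col + BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Depthwise 1-D convolution: one kernel per channel, channels do not mix.
// X: (C x T x B), W: (C x k) -> (C x T x B)
// [[Rcpp::export]]
arma::cube cpp_dwconv_fwd(const arma::cube& X, const arma::mat& W) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices, k = W.n_cols;
  const int pad = (k - 1) / 2;
  cube Y(C, T, B, fill::zeros);
  std::vector<double> xr(T), yr(T);
  for (int b = 0; b < B; ++b) {
    const mat& Xs = X.slice(b);
    mat& Ys = Y.slice(b);
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < T; ++t) xr[t] = Xs(c, t);
      std::fill(yr.begin(), yr.end(), 0.0);
      for (int d = 0; d < k; ++d) {
        const double w = W(c, d);
        const int off = d - pad;
        const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
        const double* xs = xr.data() + off;
        for (int t = t0; t < t1; ++t) yr[t] += w * xs[t];
      }
      for (int t = 0; t < T; ++t) Ys(c, t) = yr[t];
    }
  }
  return Y;
}

// Gradients of the depthwise convolution. dX is skipped (returned empty)
// when need_dx is false (the filter bank is the first layer of the model).
// [[Rcpp::export]]
Rcpp::List cpp_dwconv_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, const bool need_dx = true) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices, k = W.n_cols;
  const int pad = (k - 1) / 2;
  cube dX;
  if (need_dx) dX.zeros(C, T, B);
  mat dW(C, k, fill::zeros);
  std::vector<double> xr(T), gr(T), dxr(T);
  for (int b = 0; b < B; ++b) {
    const mat& Xs = X.slice(b);
    const mat& dYs = dY.slice(b);
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < T; ++t) { xr[t] = Xs(c, t); gr[t] = dYs(c, t); }
      if (need_dx) std::fill(dxr.begin(), dxr.end(), 0.0);
      for (int d = 0; d < k; ++d) {
        const int off = d - pad;
        const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
        const double* xs = xr.data() + off;
        const double w = W(c, d);
        double acc = 0.0;
        if (need_dx) {
          double* dxs = dxr.data() + off;
          for (int t = t0; t < t1; ++t) {
            acc += gr[t] * xs[t];
            dxs[t] += w * gr[t];
          }
        } else {
          for (int t = t0; t < t1; ++t) acc += gr[t] * xs[t];
        }
        dW(c, d) += acc;
      }
      if (need_dx) {
        mat& dXs = dX.slice(b);
        for (int t = 0; t < T; ++t) dXs(c, t) = dxr[t];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX, Rcpp::Named("dw") = dW);
}

// im2col: H (Cin x T x B) -> P ((Cin*k) x (T*B)), row r = d*Cin + cin,
// column j = b*T + t, entry H(cin, t + d - pad, b) with zero padding.
static mat im2col_time(const cube& H, const int k) {
  const int Cin = H.n_rows, T = H.n_cols, B = H.n_slices;
  const int pad = (k - 1) / 2;
  mat P(Cin * k, (size_t)T * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& Hs = H.slice(b);
    for (int d = 0; d < k; ++d) {
      const int off = d - pad;
      const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
      for (int t = t0; t < t1; ++t) {
        const size_t col = (size_t)b * T + t;
        std::memcpy(P.colptr(col) + (size_t)d * Cin, Hs.colptr(t + off),
                    Cin * sizeof(double));
      }
    }
  }
  return P;
}

// Grouped temporal convolution for one group: mixes Cin input features into
// Cout output features with time extent k, optionally fused with ReLU.
// H: (Cin x T x B), W: (Cout x Cin*k), b: (Cout) -> (Cout x T x B)
// [[Rcpp::export]]
arma::cube cpp_tconv_fwd(const arma::cube& H, const arma::mat& W,
                         const arma::vec& bias, const int k,
                         const bool relu = false) {
  const int T = H.n_cols, B = H.n_slices, Cout = W.n_rows;
  mat P = im2col_time(H, k);
  mat Ym = W * P;                       // (Cout x T*B), BLAS
  Ym.each_col() += bias;
  if (relu) Ym.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube Y(Cout, T, B);
  std::memcpy(Y.memptr(), Ym.memptr(), Ym.n_elem * sizeof(double));
  return Y;
}

// Gradients of the grouped temporal convolution.
// [[Rcpp::export]]
Rcpp::List cpp_tconv_bwd(const arma::cube& H, const arma::mat& W,
                         const int k, const arma::cube& dY) {
  const int Cin = H.n_rows, T = H.n_cols, B = H.n_slices;
  const int pad = (k - 1) / 2;
  mat P = im2col_time(H, k);
  const mat dYm((double*)dY.memptr(), dY.n_rows, (size_t)T * B, false, true);
  mat dW = dYm * P.t();
  vec db = sum(dYm, 1);
  mat dP = W.t() * dYm;                 // (Cin*k x T*B)
  cube dH(Cin, T, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat& dHs = dH.slice(b);
    for (int d = 0; d < k; ++d) {
      const int off = d - pad;
      const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
      for (int t = t0; t < t1; ++t) {
        const size_t col = (size_t)b * T + t;
        const double* src = dP.colptr(col) + (size_t)d * Cin;
        double* dst = dHs.colptr(t + off);
        for (int c = 0; c < Cin; ++c) dst[c] += src[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dH,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}
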