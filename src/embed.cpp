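// Node-wise temporal embedding for one region, whole-region forward and
// backward in C++. Each node has its own two-stage ReLU temporal
// convolution (widths C1 then C2, time extent k), softmax time attention
// and attention-weighted sum; a linear map shared within the region
// projects to the embedding length T1.
//
// Internal layout is time-major: activations are (T*B x C) matrices so the
// im2col staging copies contiguous time runs and the gemms hit BLAS with a
// large leading dimension. The heavy arithmetic runs in single precision by
// default (the training path); a double-precision path is kept for gradient
// verification. The backward pass recomputes the convolution activations
// from the cached region input instead of caching them.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// H: (T*B x Cin), time fastest within each batch block -> P: (T*B x Cin*k),
// column (d*Cin + c) = H column c shifted by (d - pad) within each block.
template <typename eT>
static Mat<eT> im2col_tm(const Mat<eT>& H, const int T, const int B,
                         const int k) {
  const int Cin = H.n_cols;
  const int pad = (k - 1) / 2;
  Mat<eT> P((size_t)T * B, Cin * k, fill::zeros);
  for (int d = 0; d < k; ++d) {
    const int off = d - pad;
    const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
    const int len = t1 - t0;
    if (len <= 0) continue;
    for (int c = 0; c < Cin; ++c) {
      eT* dst = P.colptr((size_t)d * Cin + c);
      const eT* src = H.colptr(c);
      for (int b = 0; b < B; ++b)
        std::memcpy(dst + (size_t)b * T + t0, src + (size_t)b * T + t0 + off,
                    len * sizeof(eT));
    }
  }
  return P;
}

template <typename eT>
static void col2im_tm(const Mat<eT>& dP, Mat<eT>& dH, const int T,
                      const int B, const int k) {
  const int Cin = dH.n_cols;
  const int pad = (k - 1) / 2;
  for (int d = 0; d < k; ++d) {
    const int off = d - pad;
    const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
    for (int c = 0; c < Cin; ++c) {
      const eT* src = dP.colptr((size_t)d * Cin + c);
      eT* dst = dH.colptr(c);
      for (int b = 0; b < B; ++b) {
        const eT* s = src + (size_t)b * T + t0;
        eT* dd = dst + (size_t)b * T + t0 + off;
        for (int t = 0; t < t1 - t0; ++t) dd[t] += s[t];
      }
    }
  }
}

template <typename eT>
static inline void relu_inplace(Mat<eT>& M) {
  eT* p = M.memptr();
  const size_t n = M.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < eT(0)) p[i] = eT(0);
}

// Workspace reused across nodes so the large buffers are allocated once
// per call rather than once per node.
template <typename eT>
struct EmbedWork {
  Mat<eT> H0, P1, H1, P2, H2;
  EmbedWork(const int T, const int B, const int C1, const int k) {
    const size_t TB = (size_t)T * B;
    H0.set_size(TB, 1);
    P1.set_size(TB, k);
    P2.set_size(TB, (size_t)C1 * k);
  }
};

// im2col into a preallocated buffer (zero only the padded edges).
template <typename eT>
static void im2col_tm_into(const Mat<eT>& H, Mat<eT>& P, const int T,
                           const int B, const int k) {
  const int Cin = H.n_cols;
  const int pad = (k - 1) / 2;
  for (int d = 0; d < k; ++d) {
    const int off = d - pad;
    const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
    const int len = t1 - t0;
    for (int c = 0; c < Cin; ++c) {
      eT* dst = P.colptr((size_t)d * Cin + c);
      const eT* src = H.colptr(c);
      for (int b = 0; b < B; ++b) {
        eT* db_ = dst + (size_t)b * T;
        if (t0 > 0) std::fill(db_, db_ + t0, eT(0));
        if (t1 < T) std::fill(db_ + t1, db_ + T, eT(0));
        if (len > 0)
          std::memcpy(db_ + t0, src + (size_t)b * T + t0 + off,
                      len * sizeof(eT));
      }
    }
  }
}

// Recompute both convolution stages for node j (time-major activations).
template <typename eT>
static void node_convs(const Cube<eT>& xi, const int j, const Cube<eT>& w1,
                       const Mat<eT>& b1, const Cube<eT>& w2,
                       const Mat<eT>& b2, const int k, EmbedWork<eT>& W) {
  const int T = xi.n_cols, B = xi.n_slices;
  const int C1 = w1.n_rows, C2 = w2.n_rows;
  for (int b = 0; b < B; ++b) {
    eT* dst = W.H0.memptr() + (size_t)b * T;
    for (int t = 0; t < T; ++t) dst[t] = xi(j, t, b);
  }
  im2col_tm_into(W.H0, W.P1, T, B, k);           // (TB x k)
  const Mat<eT> W1j(const_cast<eT*>(w1.slice_memptr(j)), C1, k, false, true);
  W.H1 = W.P1 * W1j.t();                         // (TB x C1)
  W.H1.each_row() += b1.col(j).t();
  relu_inplace(W.H1);
  im2col_tm_into(W.H1, W.P2, T, B, k);           // (TB x C1*k)
  const Mat<eT> W2j(const_cast<eT*>(w2.slice_memptr(j)), C2, C1 * k, false,
                    true);
  W.H2 = W.P2 * W2j.t();                         // (TB x C2)
  W.H2.each_row() += b2.col(j).t();
  relu_inplace(W.H2);
}

template <typename eT>
static Rcpp::List embed_fwd_t(const cube& xi_d, const cube& w1_d,
                              const mat& b1_d, const cube& w2_d,
                              const mat& b2_d, const mat& u_d,
                              const vec& bu_d, const mat& wl_d,
                              const vec& bl_d, const int k) {
  const Cube<eT> xi = conv_to<Cube<eT>>::from(xi_d);
  const Cube<eT> w1 = conv_to<Cube<eT>>::from(w1_d);
  const Mat<eT> b1 = conv_to<Mat<eT>>::from(b1_d);
  const Cube<eT> w2 = conv_to<Cube<eT>>::from(w2_d);
  const Mat<eT> b2 = conv_to<Mat<eT>>::from(b2_d);
  const Mat<eT> u = conv_to<Mat<eT>>::from(u_d);
  const Col<eT> bu = conv_to<Col<eT>>::from(bu_d);
  const Mat<eT> wl = conv_to<Mat<eT>>::from(wl_d);
  const Col<eT> bl = conv_to<Col<eT>>::from(bl_d);
  const int N = xi.n_rows, T = xi.n_cols, B = xi.n_slices;
  const int C2 = w2.n_rows, T1 = wl.n_rows;

  cube E(N, T1, B), S(T, B, N), H5(C2, B, N);
  EmbedWork<eT> WK(T, B, w1.n_rows, k);
  for (int j = 0; j < N; ++j) {
    node_convs(xi, j, w1, b1, w2, b2, k, WK);
    const Mat<eT>& H2 = WK.H2;
    Col<eT> sc = H2 * u.col(j);                  // TB
    sc += bu(j);
    Mat<eT> h5(C2, B);
    double* Sj = S.slice_memptr(j);
    for (int b = 0; b < B; ++b) {
      eT* blk = sc.memptr() + (size_t)b * T;
      eT mx = blk[0];
      for (int t = 1; t < T; ++t) mx = std::max(mx, blk[t]);
      eT sum = 0;
      for (int t = 0; t < T; ++t) {
        blk[t] = std::exp(blk[t] - mx);
        sum += blk[t];
      }
      for (int t = 0; t < T; ++t) {
        blk[t] /= sum;
        Sj[(size_t)b * T + t] = (double)blk[t];
      }
      h5.col(b) = H2.rows((size_t)b * T, (size_t)b * T + T - 1).t() *
        Col<eT>(blk, T);
    }
    Mat<eT> Ej = wl * h5;                        // T1 x B
    Ej.each_col() += bl;
    for (int b = 0; b < B; ++b) {
      for (int t1 = 0; t1 < T1; ++t1) E(j, t1, b) = (double)Ej(t1, b);
      for (int c = 0; c < C2; ++c) H5(c, b, j) = (double)h5(c, b);
    }
  }
  return Rcpp::List::create(Rcpp::Named("E") = E, Rcpp::Named("S") = S,
                            Rcpp::Named("H5") = H5);
}

// [[Rcpp::export]]
Rcpp::List cpp_embed_fwd(const arma::cube& xi, const arma::cube& w1,
                         const arma::mat& b1, const arma::cube& w2,
                         const arma::mat& b2, const arma::mat& u,
                         const arma::vec& bu, const arma::mat& wl,
                         const arma::vec& bl, const int k,
                         const bool single = true) {
  if (single)
    return embed_fwd_t<float>(xi, w1, b1, w2, b2, u, bu, wl, bl, k);
  return embed_fwd_t<double>(xi, w1, b1, w2, b2, u, bu, wl, bl, k);
}

template <typename eT>
static Rcpp::List embed_bwd_t(const cube& xi_d, const cube& w1_d,
                              const mat& b1_d, const cube& w2_d,
                              const mat& b2_d, const mat& u_d,
                              const vec& bu_d, const mat& wl_d,
                              const cube& S_d, const cube& H5_d,
                              const cube& dE_d, const int k) {
  const Cube<eT> xi = conv_to<Cube<eT>>::from(xi_d);
  const Cube<eT> w1 = conv_to<Cube<eT>>::from(w1_d);
  const Mat<eT> b1 = conv_to<Mat<eT>>::from(b1_d);
  const Cube<eT> w2 = conv_to<Cube<eT>>::from(w2_d);
  const Mat<eT> b2 = conv_to<Mat<eT>>::from(b2_d);
  const Mat<eT> u = conv_to<Mat<eT>>::from(u_d);
  const Mat<eT> wl = conv_to<Mat<eT>>::from(wl_d);
  const Cube<eT> S = conv_to<Cube<eT>>::from(S_d);
  const Cube<eT> H5 = conv_to<Cube<eT>>::from(H5_d);
  const Cube<eT> dE = conv_to<Cube<eT>>::from(dE_d);
  const int N = xi.n_rows, T = xi.n_cols, B = xi.n_slices;
  const int C1 = w1.n_rows, C2 = w2.n_rows, T1 = wl.n_rows;

  Cube<eT> dxi(N, T, B, fill::zeros);
  Cube<eT> dw1(C1, k, N, fill::zeros), dw2(C2, C1 * k, N, fill::zeros);
  Mat<eT> db1(C1, N, fill::zeros), db2(C2, N, fill::zeros);
  Mat<eT> du(C2, N, fill::zeros);
  Col<eT> dbu(N, fill::zeros);
  Mat<eT> dwl(T1, C2, fill::zeros);
  Col<eT> dbl(T1, fill::zeros);
  EmbedWork<eT> WK(T, B, C1, k);
  Mat<eT> dH2((size_t)T * B, C2), dP2, dH1((size_t)T * B, C1);
  Mat<eT> dP1, dH0((size_t)T * B, 1);
  Col<eT> dsc((size_t)T * B);

  for (int j = 0; j < N; ++j) {
    node_convs(xi, j, w1, b1, w2, b2, k, WK);
    const Mat<eT>& H1 = WK.H1;
    const Mat<eT>& H2 = WK.H2;
    Mat<eT> dEj(T1, B);
    for (int b = 0; b < B; ++b)
      for (int t1 = 0; t1 < T1; ++t1) dEj(t1, b) = dE(j, t1, b);
    const Mat<eT> h5(const_cast<eT*>(H5.slice_memptr(j)), C2, B, false, true);
    dwl += dEj * h5.t();
    dbl += sum(dEj, 1);
    Mat<eT> dh5 = wl.t() * dEj;                  // C2 x B
    const eT* Sj = S.slice_memptr(j);
    for (int b = 0; b < B; ++b) {
      const size_t r0 = (size_t)b * T;
      const Col<eT> sb(const_cast<eT*>(Sj) + r0, T, false, true);
      // dS_t = h2(t,:) . dh5_b ; dH2(t,:) = S_t * dh5_b
      Col<eT> dS = H2.rows(r0, r0 + T - 1) * dh5.col(b);
      const eT dp = dot(sb, dS);
      for (int t = 0; t < T; ++t)
        dsc(r0 + t) = sb(t) * (dS(t) - dp);      // softmax backward
      for (int c = 0; c < C2; ++c) {             // dH2(t,:) = S_t * dh5_b
        eT* col = dH2.colptr(c) + r0;
        const eT v = dh5(c, b);
        const eT* sp = sb.memptr();
        for (int t = 0; t < T; ++t) col[t] = sp[t] * v;
      }
    }
    du.col(j) += H2.t() * dsc;
    dbu(j) += accu(dsc);
    dH2 += dsc * u.col(j).t();
    // relu mask of stage 2
    {
      eT* p = dH2.memptr(); const eT* h = H2.memptr();
      for (size_t i = 0; i < dH2.n_elem; ++i) if (h[i] <= eT(0)) p[i] = eT(0);
    }
    // conv2 backward (P2 for this node is still in the workspace)
    dw2.slice(j) += dH2.t() * WK.P2;
    db2.col(j) += sum(dH2, 0).t();
    const Mat<eT> W2j(const_cast<eT*>(w2.slice_memptr(j)), C2, C1 * k,
                      false, true);
    dP2 = dH2 * W2j;                             // (TB x C1*k)
    dH1.zeros();
    col2im_tm(dP2, dH1, T, B, k);
    {
      eT* p = dH1.memptr(); const eT* h = H1.memptr();
      for (size_t i = 0; i < dH1.n_elem; ++i) if (h[i] <= eT(0)) p[i] = eT(0);
    }
    // conv1 backward (P1/H0 for this node are still in the workspace)
    dw1.slice(j) += dH1.t() * WK.P1;
    db1.col(j) += sum(dH1, 0).t();
    const Mat<eT> W1j(const_cast<eT*>(w1.slice_memptr(j)), C1, k, false,
                      true);
    dP1 = dH1 * W1j;                             // (TB x k)
    dH0.zeros();
    col2im_tm(dP1, dH0, T, B, k);
    for (int b = 0; b < B; ++b) {
      const eT* src = dH0.memptr() + (size_t)b * T;
      for (int t = 0; t < T; ++t) dxi(j, t, b) = src[t];
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("dxi") = conv_to<cube>::from(dxi),
    Rcpp::Named("dw1") = conv_to<cube>::from(dw1),
    Rcpp::Named("db1") = conv_to<mat>::from(db1),
    Rcpp::Named("dw2") = conv_to<cube>::from(dw2),
    Rcpp::Named("db2") = conv_to<mat>::from(db2),
    Rcpp::Named("du") = conv_to<mat>::from(du),
    Rcpp::Named("dbu") = conv_to<vec>::from(dbu),
    Rcpp::Named("dwl") = conv_to<mat>::from(dwl),
    Rcpp::Named("dbl") = conv_to<vec>::from(dbl));
}

// [[Rcpp::export]]
Rcpp::List cpp_embed_bwd(const arma::cube& xi, const arma::cube& w1,
                         const arma::mat& b1, const arma::cube& w2,
                         const arma::mat& b2, const arma::mat& u,
                         const arma::vec& bu, const arma::mat& wl,
                         const arma::cube& S, const arma::cube& H5,
                         const arma::cube& dE, const int k,
                         const bool single = true) {
  if (single)
    return embed_bwd_t<float>(xi, w1, b1, w2, b2, u, bu, wl, S, H5, dE, k);
  return embed_bwd_t<double>(xi, w1, b1, w2, b2, u, bu, wl, S, H5, dE, k);
}
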