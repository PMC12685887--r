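#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps cross the R/C++ boundary as numeric arrays with dim (C, H, W, B).
// Convolutions are "same" (pad = (k-1)/2) with either zero or reflect padding
// (reflect never repeats the edge sample: index -1 maps to 1).

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// im2col: output K x N with K = C*k*k, N = H*W*B.
// Row index r = c + C*(ki + k*kj); column index j = h + H*w + H*W*b.
static void im2col_buf(const double* x, double* colp, int C, int H, int W,
                       int B, int k, int pad_zero) {
  const int p = (k - 1) / 2;
  const int K = C * k * k;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (long)C * H * W * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const long j = h + (long)H * w + (long)H * W * b;
        double* col = colp + (long)K * j;
        for (int kj = 0; kj < k; ++kj) {
          int ws = w + kj - p;
          for (int ki = 0; ki < k; ++ki) {
            int hs = h + ki - p;
            int hh = hs, ww = ws;
            if (pad_zero) {
              if (hs < 0 || hs >= H || ws < 0 || ws >= W) continue;
            } else {
              hh = reflect_idx(hs, H);
              ww = reflect_idx(ws, W);
            }
            const double* src = xb + (long)C * (hh + (long)H * ww);
            double* dst = col + C * (ki + k * kj);
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add dcols back onto the input grid.
static void col2im_adj(const arma::mat& dcols, double* dx,
                       int C, int H, int W, int B, int k, int pad_zero) {
  const int p = (k - 1) / 2;
  for (int b = 0; b < B; ++b) {
    double* xb = dx + (long)C * H * W * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const long j = h + (long)H * w + (long)H * W * b;
        const double* col = dcols.colptr(j);
        for (int kj = 0; kj < k; ++kj) {
          int ws = w + kj - p;
          for (int ki = 0; ki < k; ++ki) {
            int hs = h + ki - p;
            int hh = hs, ww = ws;
            if (pad_zero) {
              if (hs < 0 || hs >= H || ws < 0 || ws >= W) continue;
            } else {
              hh = reflect_idx(hs, H);
              ww = reflect_idx(ws, W);
            }
            double* dst = xb + (long)C * (hh + (long)H * ww);
            const double* src = col + C * (ki + k * kj);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

static void get_dims4(const NumericVector& x, int& C, int& H, int& W, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("feature map must have dim (C, H, W, B)");
  C = d[0]; H = d[1]; W = d[2]; B = d[3];
}

// Forward conv; returns the output and the im2col column matrix so the
// backward pass can reuse it (k = 1 needs no column matrix).
// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, NumericMatrix Wm, NumericVector bias,
                    int k, bool pad_zero) {
  int C, H, W, B;
  get_dims4(x, C, H, W, B);
  const int Cout = Wm.nrow();
  if (Wm.ncol() != C * k * k) stop("weight/input channel mismatch");
  const long N = (long)H * W * B;
  arma::mat Wa(Wm.begin(), Cout, C * k * k, false);
  NumericVector out(Cout * N);
  arma::mat outm(out.begin(), Cout, N, false);
  RObject cols_out = R_NilValue;
  if (k == 1) {
    arma::mat xm(x.begin(), C, N, false);
    outm = Wa * xm;
  } else {
    NumericMatrix cols(C * k * k, N);
    im2col_buf(x.begin(), cols.begin(), C, H, W, B, k, pad_zero ? 1 : 0);
    arma::mat ca(cols.begin(), C * k * k, N, false);
    outm = Wa * ca;
    cols_out = cols;
  }
  outm.each_col() += arma::vec(bias.begin(), Cout, false);
  out.attr("dim") = IntegerVector::create(Cout, H, W, B);
  return List::create(_["out"] = out, _["cols"] = cols_out);
}

// Backward conv reusing the forward column matrix.
// [[Rcpp::export]]
List cpp_conv2d_bwd(RObject cols, NumericMatrix Wm, NumericVector dout,
                    IntegerVector dims, int k, bool pad_zero) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wm.nrow();
  const long N = (long)H * W * B;
  arma::mat Wa(Wm.begin(), Cout, C * k * k, false);
  arma::mat doutm(dout.begin(), Cout, N, false);
  NumericMatrix dW(Cout, C * k * k);
  arma::mat dWa(dW.begin(), Cout, C * k * k, false);
  NumericVector db(Cout);
  arma::vec dba(db.begin(), Cout, false);
  dba = arma::sum(doutm, 1);
  NumericVector dx((R_xlen_t)C * N);
  dx.attr("dim") = dims;
  if (k == 1) {
    stop("k = 1 backward is handled in R");
  } else {
    NumericMatrix colm(cols);
    arma::mat ca(colm.begin(), C * k * k, N, false);
    dWa = doutm * ca.t();
    arma::mat dcols = Wa.t() * doutm;
    col2im_adj(dcols, dx.begin(), C, H, W, B, k, pad_zero ? 1 : 0);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Depthwise convolution with one shared fixed k x k stencil (the Laplacian).
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericMatrix kern, bool pad_zero) {
  int C, H, W, B;
  get_dims4(x, C, H, W, B);
  const int k = kern.nrow();
  const int p = (k - 1) / 2;
  NumericVector out(x.size());
  out.attr("dim") = IntegerVector::create(C, H, W, B);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    const long off = (long)C * H * W * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* dst = op + off + (long)C * (h + (long)H * w);
        for (int kj = 0; kj < k; ++kj) {
          int ws = w + kj - p;
          for (int ki = 0; ki < k; ++ki) {
            int hs = h + ki - p;
            int hh = hs, ww = ws;
            if (pad_zero) {
              if (hs < 0 || hs >= H || ws < 0 || ws >= W) continue;
            } else {
              hh = reflect_idx(hs, H);
              ww = reflect_idx(ws, W);
            }
            const double kv = kern(ki, kj);
            if (kv == 0.0) continue;
            const double* src = xp + off + (long)C * (hh + (long)H * ww);
            for (int c = 0; c < C; ++c) dst[c] += kv * src[c];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of the depthwise convolution (gradient w.r.t. its input; the
// stencil itself is fixed and receives no gradient).
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_bwd(NumericVector dout, NumericMatrix kern, bool pad_zero) {
  int C, H, W, B;
  get_dims4(dout, C, H, W, B);
  const int k = kern.nrow();
  const int p = (k - 1) / 2;
  NumericVector dx(dout.size());
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  for (int b = 0; b < B; ++b) {
    const long off = (long)C * H * W * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* src = dp + off + (long)C * (h + (long)H * w);
        for (int kj = 0; kj < k; ++kj) {
          int ws = w + kj - p;
          for (int ki = 0; ki < k; ++ki) {
            int hs = h + ki - p;
            int hh = hs, ww = ws;
            if (pad_zero) {
              if (hs < 0 || hs >= H || ws < 0 || ws >= W) continue;
            } else {
              hh = reflect_idx(hs, H);
              ww = reflect_idx(ws, W);
            }
            const double kv = kern(ki, kj);
            if (kv == 0.0) continue;
            double* dst = xp + off + (long)C * (hh + (long)H * ww);
            for (int c = 0; c < C; ++c) dst[c] += kv * src[c];
          }
        }
      }
    }
  }
  return dx;
}

// Batched scaled-dot-product attention over S = (windows x heads) slices.
// Q, K, V: (T, dh, S) arrays. Returns A (T, T, S) row-softmax attention and
// O (T, dh, S) weighted values.
// [[Rcpp::export]]
List cpp_attn_fwd(NumericVector Q, NumericVector K, NumericVector V) {
  IntegerVector d = Q.attr("dim");
  const int T = d[0], dh = d[1], S = d[2];
  const double sc = 1.0 / std::sqrt((double)dh);
  NumericVector A((R_xlen_t)T * T * S), O(Q.size());
  A.attr("dim") = IntegerVector::create(T, T, S);
  O.attr("dim") = IntegerVector::create(T, dh, S);
  for (int s = 0; s < S; ++s) {
    arma::mat Qs(const_cast<double*>(Q.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat Ks(const_cast<double*>(K.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat Vs(const_cast<double*>(V.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat As(A.begin() + (long)T * T * s, T, T, false);
    arma::mat Os(O.begin() + (long)T * dh * s, T, dh, false);
    As = Qs * Ks.t() * sc;
    for (int i = 0; i < T; ++i) {
      arma::rowvec r = As.row(i);
      r -= r.max();
      r = arma::exp(r);
      As.row(i) = r / arma::accu(r);
    }
    Os = As * Vs;
  }
  return List::create(_["A"] = A, _["O"] = O);
}

// [[Rcpp::export]]
List cpp_attn_bwd(NumericVector Q, NumericVector K, NumericVector V,
                  NumericVector A, NumericVector dO) {
  IntegerVector d = Q.attr("dim");
  const int T = d[0], dh = d[1], S = d[2];
  const double sc = 1.0 / std::sqrt((double)dh);
  NumericVector dQ(Q.size()), dK(Q.size()), dV(Q.size());
  dQ.attr("dim") = dK.attr("dim") = dV.attr("dim") =
    IntegerVector::create(T, dh, S);
  for (int s = 0; s < S; ++s) {
    arma::mat Qs(const_cast<double*>(Q.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat Ks(const_cast<double*>(K.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat Vs(const_cast<double*>(V.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat As(const_cast<double*>(A.begin()) + (long)T * T * s, T, T, false);
    arma::mat dOs(const_cast<double*>(dO.begin()) + (long)T * dh * s, T, dh, false);
    arma::mat dQs(dQ.begin() + (long)T * dh * s, T, dh, false);
    arma::mat dKs(dK.begin() + (long)T * dh * s, T, dh, false);
    arma::mat dVs(dV.begin() + (long)T * dh * s, T, dh, false);
    arma::mat dA = dOs * Vs.t();
    dVs = As.t() * dOs;
    arma::vec rs = arma::sum(dA % As, 1);
    arma::mat dS = As % (dA.each_col() - rs);
    dQs = dS * Ks * sc;
    dKs = dS.t() * Qs * sc;
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
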