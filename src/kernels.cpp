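// Hot numerical kernels: im2col / col2im for the convolutional spatial
// module and the recurrent-cell loops (vanilla RNN, GRU, LSTM) with
// backpropagation through time. Array layouts match the R callers:
// images are (batch, height, width, channel), sequences (batch, step,
// feature), both column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat as_mat_view(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false);
}

// X: (B,H,W,C) -> (B*H2*W2) x (kh*kw*C); offsets ordered i fastest, then j,
// then channel — identical to the R reference.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int kh, int kw, int stride,
                         int pad) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], H = d[1], W = d[2], C = d[3];
  const int H2 = (H + 2 * pad - kh) / stride + 1;
  const int W2 = (W + 2 * pad - kw) / stride + 1;
  const int rows = B * H2 * W2;
  NumericMatrix out(rows, kh * kw * C);
  const double* x = X.begin();
  double* o = out.begin();
  const long BH = (long)B * H, BHW = (long)B * H * W;
  int colblk = 0;
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int c = 0; c < C; ++c) {
        double* dst = o + (long)(colblk * C + c) * rows;
        for (int w2 = 0; w2 < W2; ++w2) {
          const int wsrc = j + w2 * stride - pad;
          for (int h2 = 0; h2 < H2; ++h2) {
            const int hsrc = i + h2 * stride - pad;
            double* dcol = dst + ((long)w2 * H2 + h2) * B;
            if (hsrc < 0 || hsrc >= H || wsrc < 0 || wsrc >= W) {
              std::memset(dcol, 0, sizeof(double) * B);
            } else {
              const double* src = x + (long)c * BHW + (long)wsrc * BH +
                                  (long)hsrc * B;
              std::memcpy(dcol, src, sizeof(double) * B);
            }
          }
        }
      }
      ++colblk;
    }
  }
  return out;
}

// scatter-add the columns back onto the (B,H,W,C) input gradient
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dXcol, IntegerVector dims, int kh,
                         int kw, int stride, int pad) {
  const int B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int H2 = (H + 2 * pad - kh) / stride + 1;
  const int W2 = (W + 2 * pad - kw) / stride + 1;
  const int rows = B * H2 * W2;
  NumericVector dX((long)B * H * W * C);
  dX.attr("dim") = dims;
  double* out = dX.begin();
  const double* g = dXcol.begin();
  const long BH = (long)B * H, BHW = (long)B * H * W;
  int colblk = 0;
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int c = 0; c < C; ++c) {
        const double* src0 = g + (long)(colblk * C + c) * rows;
        for (int w2 = 0; w2 < W2; ++w2) {
          const int wsrc = j + w2 * stride - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int h2 = 0; h2 < H2; ++h2) {
            const int hsrc = i + h2 * stride - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            const double* src = src0 + ((long)w2 * H2 + h2) * B;
            double* dst = out + (long)c * BHW + (long)wsrc * BH +
                          (long)hsrc * B;
            for (int b = 0; b < B; ++b) dst[b] += src[b];
          }
        }
      }
      ++colblk;
    }
  }
  return dX;
}

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// copy a (B x Hd) slab for step t out of a (B, T, Hd) R array
static arma::mat step_of(const double* x, int B, int T, int Hd, int t) {
  arma::mat out(B, Hd);
  for (int h = 0; h < Hd; ++h) {
    std::memcpy(out.colptr(h), x + (long)h * B * T + (long)t * B,
                sizeof(double) * B);
  }
  return out;
}

static void set_step(double* x, int B, int T, int Hd, int t,
                     const arma::mat& v) {
  for (int h = 0; h < Hd; ++h) {
    std::memcpy(x + (long)h * B * T + (long)t * B, v.colptr(h),
                sizeof(double) * B);
  }
}

// X: (B,T,D); Wx: D x (ng*Hd); Wh: Hd x (ng*Hd); b: ng*Hd
// cell: 0 = rnn, 1 = gru, 2 = lstm. Returns the full hidden sequence H as a
// (B,T,Hd) array plus the gate caches backward needs (each (B,T,Hd)).
// [[Rcpp::export]]
List cpp_rnn_forward(NumericVector X, NumericMatrix Wx, NumericMatrix Wh,
                     NumericVector b, int cell) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], T = d[1], D = d[2];
  const int ng = cell == 0 ? 1 : (cell == 1 ? 3 : 4);
  const int Hd = Wh.nrow();
  arma::mat Xm(const_cast<double*>(X.begin()), (long)B * T, D, false);
  arma::mat aWx = as_mat_view(Wx), aWh = as_mat_view(Wh);
  arma::rowvec ab(const_cast<double*>(b.begin()), ng * Hd, false);
  arma::mat pre = Xm * aWx;
  pre.each_row() += ab;

  IntegerVector hdim = IntegerVector::create(B, T, Hd);
  NumericVector Hout((long)B * T * Hd);
  Hout.attr("dim") = hdim;
  List caches;
  arma::mat h(B, Hd, arma::fill::zeros);

  auto gate = [&](const arma::mat& block, int g) {
    return block.cols(g * Hd, (g + 1) * Hd - 1);
  };

  if (cell == 1) { // gru
    NumericVector Rg((long)B * T * Hd), Zg((long)B * T * Hd),
        Cg((long)B * T * Hd);
    Rg.attr("dim") = hdim; Zg.attr("dim") = hdim; Cg.attr("dim") = hdim;
    arma::mat Whr = aWh.cols(0, Hd - 1), Whz = aWh.cols(Hd, 2 * Hd - 1),
              Whc = aWh.cols(2 * Hd, 3 * Hd - 1);
    for (int t = 0; t < T; ++t) {
      arma::mat px = pre.rows((long)t * B, (long)(t + 1) * B - 1);
      arma::mat r = sigm(gate(px, 0) + h * Whr);
      arma::mat z = sigm(gate(px, 1) + h * Whz);
      arma::mat c = arma::tanh(gate(px, 2) + (r % h) * Whc);
      h = (1.0 - z) % h + z % c;
      set_step(Rg.begin(), B, T, Hd, t, r);
      set_step(Zg.begin(), B, T, Hd, t, z);
      set_step(Cg.begin(), B, T, Hd, t, c);
      set_step(Hout.begin(), B, T, Hd, t, h);
    }
    caches = List::create(Named("R") = Rg, Named("Z") = Zg,
                          Named("C") = Cg);
  } else if (cell == 0) { // vanilla rnn
    for (int t = 0; t < T; ++t) {
      arma::mat px = pre.rows((long)t * B, (long)(t + 1) * B - 1);
      h = arma::tanh(px + h * aWh);
      set_step(Hout.begin(), B, T, Hd, t, h);
    }
    caches = List::create();
  } else { // lstm
    NumericVector Ig((long)B * T * Hd), Fg((long)B * T * Hd),
        Og((long)B * T * Hd), Gg((long)B * T * Hd), Cs((long)B * T * Hd);
    Ig.attr("dim") = hdim; Fg.attr("dim") = hdim; Og.attr("dim") = hdim;
    Gg.attr("dim") = hdim; Cs.attr("dim") = hdim;
    arma::mat cst(B, Hd, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      arma::mat a = pre.rows((long)t * B, (long)(t + 1) * B - 1) + h * aWh;
      arma::mat i = sigm(gate(a, 0));
      arma::mat f = sigm(gate(a, 1));
      arma::mat o = sigm(gate(a, 2));
      arma::mat g = arma::tanh(gate(a, 3));
      cst = f % cst + i % g;
      h = o % arma::tanh(cst);
      set_step(Ig.begin(), B, T, Hd, t, i);
      set_step(Fg.begin(), B, T, Hd, t, f);
      set_step(Og.begin(), B, T, Hd, t, o);
      set_step(Gg.begin(), B, T, Hd, t, g);
      set_step(Cs.begin(), B, T, Hd, t, cst);
      set_step(Hout.begin(), B, T, Hd, t, h);
    }
    caches = List::create(Named("I") = Ig, Named("F") = Fg,
                          Named("O") = Og, Named("G") = Gg,
                          Named("Cs") = Cs);
  }
  return List::create(Named("H") = Hout, Named("caches") = caches);
}

// dH: (B,T,Hd) gradient of the full hidden sequence. X, Wx, Wh as in
// forward; caches from cpp_rnn_forward (which also returned H).
// [[Rcpp::export]]
List cpp_rnn_backward(NumericVector dH, NumericVector X, NumericVector Hseq,
                      NumericMatrix Wx, NumericMatrix Wh, List caches,
                      int cell) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], T = d[1], D = d[2];
  const int ng = cell == 0 ? 1 : (cell == 1 ? 3 : 4);
  const int Hd = Wh.nrow();
  arma::mat Xm(const_cast<double*>(X.begin()), (long)B * T, D, false);
  arma::mat aWh = as_mat_view(Wh);
  arma::mat dPre((long)B * T, ng * Hd, arma::fill::zeros);
  arma::mat dWh(Hd, ng * Hd, arma::fill::zeros);
  const double* hseq = Hseq.begin();
  const double* dh_all = dH.begin();

  arma::mat dh = step_of(dh_all, B, T, Hd, T - 1);
  if (cell == 1) {
    const NumericVector Rg = caches["R"], Zg = caches["Z"], Cg = caches["C"];
    arma::mat Whr = aWh.cols(0, Hd - 1), Whz = aWh.cols(Hd, 2 * Hd - 1),
              Whc = aWh.cols(2 * Hd, 3 * Hd - 1);
    arma::mat dWhr(Hd, Hd, arma::fill::zeros),
        dWhz(Hd, Hd, arma::fill::zeros), dWhc(Hd, Hd, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat hp = t > 0 ? step_of(hseq, B, T, Hd, t - 1)
                           : arma::mat(B, Hd, arma::fill::zeros);
      arma::mat r = step_of(Rg.begin(), B, T, Hd, t);
      arma::mat z = step_of(Zg.begin(), B, T, Hd, t);
      arma::mat c = step_of(Cg.begin(), B, T, Hd, t);
      arma::mat dz = dh % (c - hp);
      arma::mat dc = dh % z;
      arma::mat dhp = dh % (1.0 - z);
      arma::mat dac = dc % (1.0 - c % c);
      arma::mat drh = dac * Whc.t();
      arma::mat dr = drh % hp;
      dhp += drh % r;
      arma::mat dar = dr % r % (1.0 - r);
      arma::mat daz = dz % z % (1.0 - z);
      dhp += dar * Whr.t() + daz * Whz.t();
      dWhr += hp.t() * dar;
      dWhz += hp.t() * daz;
      dWhc += (r % hp).t() * dac;
      dPre.rows((long)t * B, (long)(t + 1) * B - 1) =
          arma::join_rows(dar, daz, dac);
      dh = dhp;
      if (t > 0) dh += step_of(dh_all, B, T, Hd, t - 1);
    }
    dWh = arma::join_rows(dWhr, dWhz, dWhc);
  } else if (cell == 0) {
    for (int t = T - 1; t >= 0; --t) {
      arma::mat h = step_of(hseq, B, T, Hd, t);
      arma::mat da = dh % (1.0 - h % h);
      arma::mat hp = t > 0 ? step_of(hseq, B, T, Hd, t - 1)
                           : arma::mat(B, Hd, arma::fill::zeros);
      dWh += hp.t() * da;
      dPre.rows((long)t * B, (long)(t + 1) * B - 1) = da;
      dh = da * aWh.t();
      if (t > 0) dh += step_of(dh_all, B, T, Hd, t - 1);
    }
  } else {
    const NumericVector Ig = caches["I"], Fg = caches["F"], Og = caches["O"],
                        Gg = caches["G"], Cs = caches["Cs"];
    arma::mat dcs(B, Hd, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat i = step_of(Ig.begin(), B, T, Hd, t);
      arma::mat f = step_of(Fg.begin(), B, T, Hd, t);
      arma::mat o = step_of(Og.begin(), B, T, Hd, t);
      arma::mat g = step_of(Gg.begin(), B, T, Hd, t);
      arma::mat cst = step_of(Cs.begin(), B, T, Hd, t);
      arma::mat cprev = t > 0 ? step_of(Cs.begin(), B, T, Hd, t - 1)
                              : arma::mat(B, Hd, arma::fill::zeros);
      arma::mat tc = arma::tanh(cst);
      arma::mat dout = dh % tc;
      dcs += dh % o % (1.0 - tc % tc);
      arma::mat di = dcs % g, df = dcs % cprev, dg = dcs % i;
      dcs = dcs % f;
      arma::mat da = arma::join_rows(
          arma::join_rows(di % i % (1.0 - i), df % f % (1.0 - f)),
          arma::join_rows(dout % o % (1.0 - o), dg % (1.0 - g % g)));
      arma::mat hp = t > 0 ? step_of(hseq, B, T, Hd, t - 1)
                           : arma::mat(B, Hd, arma::fill::zeros);
      dWh += hp.t() * da;
      dPre.rows((long)t * B, (long)(t + 1) * B - 1) = da;
      dh = da * aWh.t();
      if (t > 0) dh += step_of(dh_all, B, T, Hd, t - 1);
    }
  }
  arma::mat dWx = Xm.t() * dPre;
  arma::rowvec db = arma::sum(dPre, 0);
  return List::create(Named("Wx") = wrap(dWx), Named("Wh") = wrap(dWh),
                      Named("b") = NumericVector(db.begin(), db.end()));
}

// elementwise helpers, kept in compiled code because they sit on the hot
// path of every convolutional layer

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out = clone(x);
  double* p = out.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dY, NumericVector Xin) {
  NumericVector out = clone(dY);
  double* p = out.begin();
  const double* x = Xin.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (x[i] <= 0) p[i] = 0;
  return out;
}

// Y (n x k) + bias recycled over rows, in one pass
// [[Rcpp::export]]
NumericMatrix cpp_add_bias(NumericMatrix Y, NumericVector b) {
  NumericMatrix out = clone(Y);
  const int n = out.nrow(), k = out.ncol();
  for (int j = 0; j < k; ++j) {
    double* col = out.begin() + (long)j * n;
    const double bj = b[j];
    for (int i = 0; i < n; ++i) col[i] += bj;
  }
  return out;
}

// fused convolution: im2col + matmul + bias in one call, nothing large
// crosses back into R except the output map
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector X, NumericMatrix K, NumericVector b,
                           int kh, int kw, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], H = d[1], W = d[2];
  const int H2 = (H + 2 * pad - kh) / stride + 1;
  const int W2 = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix Xcol = cpp_im2col(X, kh, kw, stride, pad);
  arma::mat aX = as_mat_view(Xcol), aK = as_mat_view(K);
  arma::mat Y = aX * aK;
  arma::rowvec ab(const_cast<double*>(b.begin()), b.size(), false);
  Y.each_row() += ab;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(B, H2, W2, K.ncol());
  return out;
}

// fused backward: recomputes im2col from X (cheaper than holding the column
// matrix alive between passes), returns dX, dK, db
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector X, NumericMatrix K, NumericVector dY,
                  int kh, int kw, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  IntegerVector dyd = dY.attr("dim");
  const long rows = (long)dyd[0] * dyd[1] * dyd[2];
  NumericMatrix Xcol = cpp_im2col(X, kh, kw, stride, pad);
  arma::mat aX = as_mat_view(Xcol), aK = as_mat_view(K);
  arma::mat dYm(const_cast<double*>(dY.begin()), rows, dyd[3], false);
  arma::mat dK = aX.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dXcol = dYm * aK.t();
  NumericMatrix dXcol_r(dXcol.n_rows, dXcol.n_cols);
  std::memcpy(dXcol_r.begin(), dXcol.memptr(),
              sizeof(double) * dXcol.n_elem);
  NumericVector dX = cpp_col2im(dXcol_r, d, kh, kw, stride, pad);
  return List::create(Named("dX") = dX, Named("dK") = wrap(dK),
                      Named("db") = NumericVector(db.begin(), db.end()));
}
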