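// Minimal conv-net primitives (valid 2-D convolution, non-overlapping average
// pooling) used by the shallow EEG-identification network. Batches are passed
// as 4-D arrays dim = (H, W, C, B); convolution is implemented as im2col + GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fill P (kh*kw*Cin x oh*ow) with sliding 5x5 (generally kh x kw) patches of
// one sample, column-major over output positions, channel-major over rows.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int oh, int ow, mat& P) {
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      int col = oc * oh + orow;
      double* pcol = P.colptr(col);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kc = 0; kc < kw; ++kc) {
          const double* xcol = xc + (size_t)(oc + kc) * H + orow;
          for (int kr = 0; kr < kh; ++kr, ++r) pcol[r] = xcol[kr];
        }
      }
    }
  }
}

static Rcpp::NumericVector make4d(int d1, int d2, int d3, int d4) {
  Rcpp::NumericVector v((size_t)d1 * d2 * d3 * d4);
  v.attr("dim") = Rcpp::IntegerVector::create(d1, d2, d3, d4);
  return v;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv_forward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                     Rcpp::NumericVector bias) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) Rcpp::stop("channel mismatch between input and kernel");
  int oh = H - kh + 1, ow = W - kw + 1;
  // kernel as (Cout x kh*kw*Cin), rows follow im2col row order
  mat Wm(Cout, kh * kw * Cin);
  for (int co = 0; co < Cout; ++co) {
    int r = 0;
    for (int c = 0; c < Cin; ++c)
      for (int kc = 0; kc < kw; ++kc)
        for (int kr = 0; kr < kh; ++kr, ++r)
          Wm(co, r) = w[kr + kh * (kc + kw * (c + (size_t)Cin * co))];
  }
  vec bv(bias.begin(), Cout);
  Rcpp::NumericVector out = make4d(oh, ow, Cout, B);
  mat P(kh * kw * Cin, oh * ow);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * H * W * C, H, W, C, kh, kw, oh, ow, P);
    mat Y = Wm * P;               // Cout x oh*ow
    Y.each_col() += bv;
    double* o = out.begin() + (size_t)b * oh * ow * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < oh * ow; ++p)
        o[p + (size_t)co * oh * ow] = Y(co, p);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                             Rcpp::NumericVector dy) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int oh = H - kh + 1, ow = W - kw + 1;
  mat Wm(Cout, kh * kw * Cin);
  for (int co = 0; co < Cout; ++co) {
    int r = 0;
    for (int c = 0; c < Cin; ++c)
      for (int kc = 0; kc < kw; ++kc)
        for (int kr = 0; kr < kh; ++kr, ++r)
          Wm(co, r) = w[kr + kh * (kc + kw * (c + (size_t)Cin * co))];
  }
  mat dWm(Cout, kh * kw * Cin, fill::zeros);
  vec db(Cout, fill::zeros);
  Rcpp::NumericVector dx = make4d(H, W, C, B);
  mat P(kh * kw * Cin, oh * ow);
  mat dY(Cout, oh * ow);
  for (int b = 0; b < B; ++b) {
    const double* dyb = dy.begin() + (size_t)b * oh * ow * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < oh * ow; ++p)
        dY(co, p) = dyb[p + (size_t)co * oh * ow];
    im2col(x.begin() + (size_t)b * H * W * C, H, W, C, kh, kw, oh, ow, P);
    dWm += dY * P.t();
    db += sum(dY, 1);
    mat dP = Wm.t() * dY;         // kh*kw*Cin x oh*ow
    double* dxb = dx.begin() + (size_t)b * H * W * C;
    // col2im: scatter-add patches back
    for (int oc = 0; oc < ow; ++oc) {
      for (int orow = 0; orow < oh; ++orow) {
        int col = oc * oh + orow;
        const double* pcol = dP.colptr(col);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          double* xc = dxb + (size_t)c * H * W;
          for (int kc = 0; kc < kw; ++kc) {
            double* xcol = xc + (size_t)(oc + kc) * H + orow;
            for (int kr = 0; kr < kh; ++kr, ++r) xcol[kr] += pcol[r];
          }
        }
      }
    }
  }
  Rcpp::NumericVector dw = make4d(kh, kw, Cin, Cout);
  for (int co = 0; co < Cout; ++co) {
    int r = 0;
    for (int c = 0; c < Cin; ++c)
      for (int kc = 0; kc < kw; ++kc)
        for (int kr = 0; kr < kh; ++kr, ++r)
          dw[kr + kh * (kc + kw * (c + (size_t)Cin * co))] = dWm(co, r);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_avgpool_forward(Rcpp::NumericVector x, int k) {
  Rcpp::IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int oh = H / k, ow = W / k;
  Rcpp::NumericVector out = make4d(oh, ow, C, B);
  double inv = 1.0 / (k * k);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (size_t)(c + (size_t)C * b) * H * W;
      double* o = out.begin() + (size_t)(c + (size_t)C * b) * oh * ow;
      for (int oc = 0; oc < ow; ++oc)
        for (int orow = 0; orow < oh; ++orow) {
          double s = 0.0;
          for (int kc = 0; kc < k; ++kc)
            for (int kr = 0; kr < k; ++kr)
              s += xi[(orow * k + kr) + (size_t)(oc * k + kc) * H];
          o[orow + (size_t)oc * oh] = s * inv;
        }
    }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_avgpool_backward(Rcpp::NumericVector dy, int k,
                                         int H, int W) {
  Rcpp::IntegerVector yd = dy.attr("dim");
  int oh = yd[0], ow = yd[1], C = yd[2], B = yd[3];
  Rcpp::NumericVector dx = make4d(H, W, C, B);
  double inv = 1.0 / (k * k);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* d = dy.begin() + (size_t)(c + (size_t)C * b) * oh * ow;
      double* o = dx.begin() + (size_t)(c + (size_t)C * b) * H * W;
      for (int oc = 0; oc < ow; ++oc)
        for (int orow = 0; orow < oh; ++orow) {
          double g = d[orow + (size_t)oc * oh] * inv;
          for (int kc = 0; kc < k; ++kc)
            for (int kr = 0; kr < k; ++kr)
              o[(orow * k + kr) + (size_t)(oc * k + kc) * H] = g;
        }
    }
  return dx;
}
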