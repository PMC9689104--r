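// Low-level tensor ops for the segmentation network.
//
// Activation tensors are R arrays laid out (H, W, C, N), column-major, so a
// (c, n) feature plane is a contiguous H x W block.  Convolution weights are
// (K, K, Cin, Cout).  Convolutions are implemented as im2col + BLAS gemm with
// the patch matrix transposed, i.e. (Ho*Wo) x (K*K*Cin), so each kernel tap
// fills one contiguous column and the gemm output is already in (Ho, Wo, Cout)
// order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int K, int stride, int pad, int dil) {
  int eff = dil * (K - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Fill the transposed patch matrix Ct ((Ho*Wo) x (K*K*Cin)) for sample n.
static void im2col_t(const double* x, int H, int W, int Cin, int n,
                     int K, int stride, int pad, int dil,
                     int Ho, int Wo, arma::mat& Ct) {
  Ct.zeros();
  const long plane = (long)H * W;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + ((long)n * Cin + c) * plane;
    for (int j = 0; j < K; ++j) {
      for (int i = 0; i < K; ++i) {
        const int r = i + K * (j + K * c);
        double* col = Ct.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dil * j;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc + (long)wi * H;
          double* dst = col + (long)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dil * i;
            if (hi < 0 || hi >= H) continue;
            dst[ho] = src[hi];
          }
        }
      }
    }
  }
}

// Scatter-add the transposed patch gradient back onto dx (col2im adjoint).
static void col2im_t(const arma::mat& dCt, int H, int W, int Cin, int n,
                     int K, int stride, int pad, int dil,
                     int Ho, int Wo, double* dx) {
  const long plane = (long)H * W;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + ((long)n * Cin + c) * plane;
    for (int j = 0; j < K; ++j) {
      for (int i = 0; i < K; ++i) {
        const int r = i + K * (j + K * c);
        const double* col = dCt.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dil * j;
          if (wi < 0 || wi >= W) continue;
          double* dstp = xc + (long)wi * H;
          const double* srcp = col + (long)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dil * i;
            if (hi < 0 || hi >= H) continue;
            dstp[hi] += srcp[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[1] != K) stop("kernel must be square");
  if (wd[2] != Cin) stop("channel mismatch between input and kernel");
  const int Ho = out_size(H, K, stride, pad, dil);
  const int Wo = out_size(W, K, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");

  NumericVector out(NumericVector((long)Ho * Wo * Cout * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (long)K * K * Cin, Cout, false);
  arma::mat Ct((long)Ho * Wo, (long)K * K * Cin);

  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin(), H, W, Cin, n, K, stride, pad, dil, Ho, Wo, Ct);
    arma::mat O(out.begin() + (long)n * Ho * Wo * Cout, (long)Ho * Wo, Cout, false, true);
    O = Ct * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int o = 0; o < Cout; ++o) O.col(o) += b[o];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad, int dil, bool need_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = dout.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = od[0], Wo = od[1];

  NumericVector dx((long)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw((long)K * K * Cin * Cout);
  dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), (long)K * K * Cin, Cout, false);
  arma::mat dWm(dw.begin(), (long)K * K * Cin, Cout, false, true);
  arma::mat Ct((long)Ho * Wo, (long)K * K * Cin);
  arma::vec db(Cout, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    arma::mat dO(const_cast<double*>(dout.begin()) + (long)n * Ho * Wo * Cout,
                 (long)Ho * Wo, Cout, false);
    im2col_t(x.begin(), H, W, Cin, n, K, stride, pad, dil, Ho, Wo, Ct);
    dWm += Ct.t() * dO;
    arma::mat dCt = dO * Wm.t();
    col2im_t(dCt, H, W, Cin, n, K, stride, pad, dil, Ho, Wo, dx.begin());
    if (need_bias) db += arma::sum(dO, 0).t();
  }
  List res = List::create(_["dx"] = dx, _["dw"] = dw);
  if (need_bias) res["db"] = NumericVector(db.begin(), db.end());
  return res;
}

// Batch normalisation over (H, W, N) per channel, biased variance.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long plane = (long)H * W;
  const double M = (double)plane * N;

  NumericVector y((long)H * W * C * N), xhat((long)H * W * C * N);
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  NumericVector mu(C), var(C);

  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((long)n * C + c) * plane;
      for (long i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / M;
    double v = s2 / M - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const long off = ((long)n * C + c) * plane;
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (long i = 0; i < plane; ++i) {
        ph[i] = (p[i] - m) * inv;
        py[i] = g * ph[i] + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dout, NumericVector xhat, NumericVector var,
                NumericVector gamma, double eps) {
  IntegerVector xd = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long plane = (long)H * W;
  const double M = (double)plane * N;

  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);

  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const long off = ((long)n * C + c) * plane;
      const double* pd = dout.begin() + off;
      const double* ph = xhat.begin() + off;
      for (long i = 0; i < plane; ++i) { sb += pd[i]; sg += pd[i] * ph[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double inv = gamma[c] / std::sqrt(var[c] + eps);
    const double a = sb / M, b = sg / M;
    for (int n = 0; n < N; ++n) {
      const long off = ((long)n * C + c) * plane;
      const double* pd = dout.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      for (long i = 0; i < plane; ++i)
        px[i] = inv * (pd[i] - a - ph[i] * b);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Apply per-channel affine using running statistics (inference mode).
// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector rmean,
                           NumericVector rvar, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long plane = (long)H * W;
  NumericVector y((long)H * W * C * N);
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], b = beta[c], m = rmean[c];
    for (int n = 0; n < N; ++n) {
      const long off = ((long)n * C + c) * plane;
      const double* p = x.begin() + off;
      double* py = y.begin() + off;
      for (long i = 0; i < plane; ++i) py[i] = g * (p[i] - m) * inv + b;
    }
  }
  return y;
}

// Max pooling with argmax cache (indices into the H x W plane).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, K, stride, pad, 1);
  const int Wo = out_size(W, K, stride, pad, 1);
  const long plane = (long)H * W, oplane = (long)Ho * Wo;

  NumericVector y(oplane * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(oplane * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((long)n * C + c) * plane;
      double* py = y.begin() + ((long)n * C + c) * oplane;
      int* pi = idx.begin() + ((long)n * C + c) * oplane;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          long barg = -1;
          for (int j = 0; j < K; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < K; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              const double v = p[hi + (long)wi * H];
              if (v > best) { best = v; barg = hi + (long)wi * H; }
            }
          }
          py[ho + (long)wo * Ho] = best;
          pi[ho + (long)wo * Ho] = (int)barg;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx,
                              IntegerVector in_dim) {
  IntegerVector od = dout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  const int H = in_dim[0], W = in_dim[1];
  const long plane = (long)H * W, oplane = (long)Ho * Wo;
  NumericVector dx(plane * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dout.begin() + ((long)n * C + c) * oplane;
      const int* pi = idx.begin() + ((long)n * C + c) * oplane;
      double* px = dx.begin() + ((long)n * C + c) * plane;
      for (long q = 0; q < oplane; ++q) px[pi[q]] += pd[q];
    }
  return dx;
}

// Bilinear x2 upsampling (half-pixel centres, clamped borders).
static void up2_axis(int Hin, int Hout, std::vector<int>& i0,
                     std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Hout); i1.resize(Hout); w1.resize(Hout);
  for (int o = 0; o < Hout; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > Hin - 1) src = Hin - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, Hin - 1);
    i0[o] = lo; i1[o] = hi; w1[o] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const long plane = (long)H * W, oplane = (long)Ho * Wo;
  NumericVector y(oplane * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_axis(H, Ho, h0, h1, hw);
  up2_axis(W, Wo, w0, w1v, ww);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((long)n * C + c) * plane;
      double* py = y.begin() + ((long)n * C + c) * oplane;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* c0 = p + (long)w0[wo] * H;
        const double* c1 = p + (long)w1v[wo] * H;
        const double bw = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const double ah = hw[ho];
          const double v0 = c0[h0[ho]] * (1 - ah) + c0[h1[ho]] * ah;
          const double v1 = c1[h0[ho]] * (1 - ah) + c1[h1[ho]] * ah;
          py[ho + (long)wo * Ho] = v0 * (1 - bw) + v1 * bw;
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dout) {
  IntegerVector od = dout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  const int H = Ho / 2, W = Wo / 2;
  const long plane = (long)H * W, oplane = (long)Ho * Wo;
  NumericVector dx(plane * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);

  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_axis(H, Ho, h0, h1, hw);
  up2_axis(W, Wo, w0, w1v, ww);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dout.begin() + ((long)n * C + c) * oplane;
      double* px = dx.begin() + ((long)n * C + c) * plane;
      for (int wo = 0; wo < Wo; ++wo) {
        const double bw = ww[wo];
        double* c0 = px + (long)w0[wo] * H;
        double* c1 = px + (long)w1v[wo] * H;
        for (int ho = 0; ho < Ho; ++ho) {
          const double ah = hw[ho];
          const double g = pd[ho + (long)wo * Ho];
          c0[h0[ho]] += g * (1 - ah) * (1 - bw);
          c0[h1[ho]] += g * ah * (1 - bw);
          c1[h0[ho]] += g * (1 - ah) * bw;
          c1[h1[ho]] += g * ah * bw;
        }
      }
    }
  return dx;
}

// Fused Adam update: m and v are mutated in place (they are owned solely by
// the optimiser state), the updated parameter vector is returned.
// [[Rcpp::export]]
NumericVector cpp_adam_update(NumericVector p, NumericVector m,
                              NumericVector v, NumericVector g,
                              double lr, double b1, double b2,
                              double eps, double c1, double c2) {
  const R_xlen_t n = p.size();
  NumericVector out = clone(p);
  double* pm = m.begin();
  double* pv = v.begin();
  const double* pg = g.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    po[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
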