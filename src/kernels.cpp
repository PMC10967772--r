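// Tensor kernels for the 3-D segmentation network and the geometry pipeline.
//
// Feature arrays are stored depth-fastest: dim = (D, H, W, C, B) in R's
// column-major order, so each (channel, batch) slice is a contiguous D*H*W
// block.  Dense convolutions run as chunked im2col + dgemm (Armadillo/BLAS);
// depthwise and transposed convolutions use direct loops whose inner axis is
// the contiguous depth run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims5 {
  int D, H, W, C, B;
  R_xlen_t spatial() const { return (R_xlen_t)D * H * W; }
};

Dims5 dims5(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5-d array (D,H,W,C,B)");
  return Dims5{d[0], d[1], d[2], d[3], d[4]};
}

inline int conv_out(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

// Fill the transposed column matrix colT (Nc x K) for output w-range
// [w0, w1) of batch b.  Row index = do + Do*(ho + Ho*(wo - w0));
// column index r = zd + kd*(zh + kh*(zw + kw*c)).
// valid output-index range [lo, hi) such that 0 <= i*s + z - p < n
inline void valid_range(int n, int s, int z, int p, int count,
                        int& lo, int& hi) {
  // i*s >= p - z  ->  i >= ceil((p - z)/s)
  int a = p - z;
  lo = a <= 0 ? 0 : (a + s - 1) / s;
  // i*s <= n - 1 - z + p  ->  i <= floor(...)
  int bmax = n - 1 - z + p;
  hi = bmax < 0 ? 0 : bmax / s + 1;
  if (lo < 0) lo = 0;
  if (hi > count) hi = count;
  if (hi < lo) hi = lo;
}

// single-precision is used for large GEMMs (training-scale feature maps);
// small tensors keep full double precision.  Threshold in MACs.
const R_xlen_t kFloatThreshold = 2000000;

template <typename MatT>
void fill_colT(const double* x, const Dims5& xd, int b,
               int kd, int kh, int kw,
               int sd, int sh, int sw,
               int pd, int ph, int pw,
               int Do, int Ho, int w0, int w1,
               MatT& colT) {
  typedef typename MatT::elem_type T;
  const R_xlen_t plane = (R_xlen_t)xd.D * xd.H;
  const R_xlen_t chan = plane * xd.W;
  const double* xb = x + (R_xlen_t)b * chan * xd.C;
  int r = 0;
  for (int c = 0; c < xd.C; ++c) {
    const double* xc = xb + (R_xlen_t)c * chan;
    for (int zw = 0; zw < kw; ++zw)
      for (int zh = 0; zh < kh; ++zh)
        for (int zd = 0; zd < kd; ++zd, ++r) {
          T* col = colT.colptr(r);
          int dlo, dhi, hlo, hhi;
          valid_range(xd.D, sd, zd, pd, Do, dlo, dhi);
          valid_range(xd.H, sh, zh, ph, Ho, hlo, hhi);
          R_xlen_t n = 0;
          for (int wo = w0; wo < w1; ++wo) {
            const int wi = wo * sw + zw - pw;
            if (wi < 0 || wi >= xd.W) {
              std::fill(col + n, col + n + (R_xlen_t)Ho * Do, T(0));
              n += (R_xlen_t)Ho * Do;
              continue;
            }
            const double* xw_ = xc + (R_xlen_t)wi * plane;
            for (int ho = 0; ho < Ho; ++ho) {
              if (ho < hlo || ho >= hhi) {
                std::fill(col + n, col + n + Do, T(0));
                n += Do;
                continue;
              }
              const int hi = ho * sh + zh - ph;
              const double* base = xw_ + (R_xlen_t)hi * xd.D + (zd - pd);
              for (int dd = 0; dd < dlo; ++dd) col[n + dd] = T(0);
              if (sd == 1) {
                for (int dd = dlo; dd < dhi; ++dd) col[n + dd] = (T)base[dd];
              } else {
                for (int dd = dlo; dd < dhi; ++dd) col[n + dd] = base[(R_xlen_t)dd * sd];
              }
              for (int dd = dhi; dd < Do; ++dd) col[n + dd] = 0.0;
              n += Do;
            }
          }
        }
  }
  (void)r;
}

// Scatter-add colT (Nc x K) back into gx for output w-range [w0,w1).
template <typename MatT>
void scatter_colT(double* gx, const Dims5& xd, int b,
                  int kd, int kh, int kw,
                  int sd, int sh, int sw,
                  int pd, int ph, int pw,
                  int Do, int Ho, int w0, int w1,
                  const MatT& colT) {
  typedef typename MatT::elem_type T;
  const R_xlen_t plane = (R_xlen_t)xd.D * xd.H;
  const R_xlen_t chan = plane * xd.W;
  double* gb = gx + (R_xlen_t)b * chan * xd.C;
  int r = 0;
  for (int c = 0; c < xd.C; ++c) {
    double* gc = gb + (R_xlen_t)c * chan;
    for (int zw = 0; zw < kw; ++zw)
      for (int zh = 0; zh < kh; ++zh)
        for (int zd = 0; zd < kd; ++zd, ++r) {
          const T* col = colT.colptr(r);
          int dlo, dhi, hlo, hhi;
          valid_range(xd.D, sd, zd, pd, Do, dlo, dhi);
          valid_range(xd.H, sh, zh, ph, Ho, hlo, hhi);
          R_xlen_t n = 0;
          for (int wo = w0; wo < w1; ++wo) {
            const int wi = wo * sw + zw - pw;
            if (wi < 0 || wi >= xd.W) { n += (R_xlen_t)Ho * Do; continue; }
            double* gw_ = gc + (R_xlen_t)wi * plane;
            for (int ho = 0; ho < Ho; ++ho) {
              if (ho < hlo || ho >= hhi) { n += Do; continue; }
              const int hi = ho * sh + zh - ph;
              double* base = gw_ + (R_xlen_t)hi * xd.D + (zd - pd);
              if (sd == 1) {
                for (int dd = dlo; dd < dhi; ++dd) base[dd] += col[n + dd];
              } else {
                for (int dd = dlo; dd < dhi; ++dd) base[(R_xlen_t)dd * sd] += col[n + dd];
              }
              n += Do;
            }
          }
        }
  }
}

int chunk_w(int Do, int Ho, int Wo, R_xlen_t K) {
  // cap the im2col buffer around 4e6 elements
  const R_xlen_t cap = 4000000;
  R_xlen_t perw = (R_xlen_t)Do * Ho * K;
  int wc = perw > 0 ? (int)std::max((R_xlen_t)1, cap / perw) : Wo;
  return std::min(wc, Wo);
}

template <typename MatT>
void conv_fwd_loop(const double* x, const Dims5& xd, const double* wptr,
                   const double* bptr, double* y,
                   int kd, int kh, int kw, int Cout,
                   int sd, int sh, int sw, int pd, int ph, int pw,
                   int Do, int Ho, int Wo) {
  typedef typename MatT::elem_type T;
  const R_xlen_t K = (R_xlen_t)kd * kh * kw * xd.C;
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  MatT Wm(K, Cout);
  for (R_xlen_t i = 0; i < K * Cout; ++i) Wm.memptr()[i] = (T)wptr[i];
  const int wchunk = chunk_w(Do, Ho, Wo, K);
  MatT colT((R_xlen_t)Do * Ho * wchunk, K);
  for (int b = 0; b < xd.B; ++b) {
    for (int w0 = 0; w0 < Wo; w0 += wchunk) {
      const int w1 = std::min(Wo, w0 + wchunk);
      const R_xlen_t Nc = (R_xlen_t)Do * Ho * (w1 - w0);
      MatT colv(colT.memptr(), Nc, K, false, true);
      fill_colT(x, xd, b, kd, kh, kw, sd, sh, sw, pd, ph, pw,
                Do, Ho, w0, w1, colv);
      MatT yc = colv * Wm; // Nc x Cout
      for (int co = 0; co < Cout; ++co) {
        double* dst = y + (R_xlen_t)b * No * Cout + (R_xlen_t)co * No +
                      (R_xlen_t)Do * Ho * w0;
        const T* src = yc.colptr(co);
        const double bb = bptr ? bptr[co] : 0.0;
        for (R_xlen_t i = 0; i < Nc; ++i) dst[i] = (double)src[i] + bb;
      }
    }
  }
}

template <typename MatT>
void conv_bwd_loop(const double* x, const Dims5& xd, const double* wptr,
                   const double* gy, double* gx, double* gw, double* gbias,
                   int kd, int kh, int kw, int Cout,
                   int sd, int sh, int sw, int pd, int ph, int pw,
                   int Do, int Ho, int Wo, bool need_gx, bool need_gw,
                   int B) {
  typedef typename MatT::elem_type T;
  const R_xlen_t K = (R_xlen_t)kd * kh * kw * xd.C;
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  MatT Wm(K, Cout);
  for (R_xlen_t i = 0; i < K * Cout; ++i) Wm.memptr()[i] = (T)wptr[i];
  MatT GW;
  if (need_gw) GW.zeros(K, Cout);
  const int wchunk = chunk_w(Do, Ho, Wo, K);
  MatT colT((R_xlen_t)Do * Ho * wchunk, K);
  for (int b = 0; b < B; ++b) {
    for (int w0 = 0; w0 < Wo; w0 += wchunk) {
      const int w1 = std::min(Wo, w0 + wchunk);
      const R_xlen_t Nc = (R_xlen_t)Do * Ho * (w1 - w0);
      MatT gyc(Nc, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* src = gy + (R_xlen_t)b * No * Cout +
                            (R_xlen_t)co * No + (R_xlen_t)Do * Ho * w0;
        T* dst = gyc.colptr(co);
        double s = 0;
        for (R_xlen_t i = 0; i < Nc; ++i) { dst[i] = (T)src[i]; s += src[i]; }
        gbias[co] += s;
      }
      if (need_gx) {
        MatT gcolT = gyc * Wm.t(); // Nc x K
        scatter_colT(gx, xd, b, kd, kh, kw, sd, sh, sw, pd, ph, pw,
                     Do, Ho, w0, w1, gcolT);
      }
      if (need_gw) {
        MatT colv(colT.memptr(), Nc, K, false, true);
        fill_colT(x, xd, b, kd, kh, kw, sd, sh, sw, pd, ph, pw,
                  Do, Ho, w0, w1, colv);
        GW += colv.t() * gyc;
      }
    }
  }
  if (need_gw)
    for (R_xlen_t i = 0; i < K * Cout; ++i) gw[i] = (double)GW.memptr()[i];
}

} // namespace

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             IntegerVector stride, IntegerVector pad) {
  Dims5 xd = dims5(x);
  IntegerVector wd = w.attr("dim"); // (kd,kh,kw,Cin,Cout)
  if (wd.size() != 5) stop("weight must be 5-d (kd,kh,kw,Cin,Cout)");
  const int kd = wd[0], kh = wd[1], kw = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != xd.C) stop("channel mismatch: input has %d, weights expect %d", xd.C, Cin);
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = conv_out(xd.D, kd, sd, pd), Ho = conv_out(xd.H, kh, sh, ph),
            Wo = conv_out(xd.W, kw, sw, pw);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("output extent < 1");
  const R_xlen_t K = (R_xlen_t)kd * kh * kw * Cin;
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(No * Cout * xd.B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, xd.B);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bptr = bv.begin(); }
  const bool pointwise = kd == 1 && kh == 1 && kw == 1 &&
    sd == 1 && sh == 1 && sw == 1 && pd == 0 && ph == 0 && pw == 0;
  const bool use_float = No * K * Cout >= kFloatThreshold;
  if (pointwise) {
    const R_xlen_t N = xd.spatial();
    if (use_float) {
      arma::fmat Wf(K, Cout);
      for (R_xlen_t i = 0; i < K * Cout; ++i) Wf.memptr()[i] = (float)w[i];
      arma::fmat xf(N, Cin);
      for (int b = 0; b < xd.B; ++b) {
        const double* xs = x.begin() + (R_xlen_t)b * N * Cin;
        for (R_xlen_t i = 0; i < N * Cin; ++i) xf.memptr()[i] = (float)xs[i];
        arma::fmat ym = xf * Wf;
        for (int co = 0; co < Cout; ++co) {
          double* dst = y.begin() + (R_xlen_t)b * N * Cout + (R_xlen_t)co * N;
          const float* src = ym.colptr(co);
          const double bb = bptr ? bptr[co] : 0.0;
          for (R_xlen_t i = 0; i < N; ++i) dst[i] = (double)src[i] + bb;
        }
      }
    } else {
      for (int b = 0; b < xd.B; ++b) {
        arma::mat xm(const_cast<double*>(x.begin()) + (R_xlen_t)b * N * Cin,
                     N, Cin, false, true);
        arma::mat ym(y.begin() + (R_xlen_t)b * N * Cout, N, Cout, false, true);
        ym = xm * Wm;
        if (bptr)
          for (int co = 0; co < Cout; ++co) ym.col(co) += bptr[co];
      }
    }
    return y;
  }
  if (use_float)
    conv_fwd_loop<arma::fmat>(x.begin(), xd, w.begin(), bptr, y.begin(),
                              kd, kh, kw, Cout, sd, sh, sw, pd, ph, pw,
                              Do, Ho, Wo);
  else
    conv_fwd_loop<arma::mat>(x.begin(), xd, w.begin(), bptr, y.begin(),
                             kd, kh, kw, Cout, sd, sh, sw, pd, ph, pw,
                             Do, Ho, Wo);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector stride, IntegerVector pad,
                    bool need_gx, bool need_gw) {
  Dims5 xd = dims5(x);
  Dims5 yd = dims5(gy);
  IntegerVector wd = w.attr("dim");
  const int kd = wd[0], kh = wd[1], kw = wd[2], Cin = wd[3], Cout = wd[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = yd.D, Ho = yd.H, Wo = yd.W;
  const R_xlen_t K = (R_xlen_t)kd * kh * kw * Cin;
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector gx, gw, gbias(Cout);
  if (need_gx) { gx = NumericVector((R_xlen_t)xd.spatial() * xd.C * xd.B); gx.attr("dim") = x.attr("dim"); }
  if (need_gw) { gw = NumericVector(K * Cout); gw.attr("dim") = w.attr("dim"); }
  arma::mat GW(need_gw ? gw.begin() : nullptr, need_gw ? K : 0,
               need_gw ? Cout : 0, false, true);

  const bool pointwise = kd == 1 && kh == 1 && kw == 1 &&
    sd == 1 && sh == 1 && sw == 1 && pd == 0 && ph == 0 && pw == 0;
  const bool use_float = No * K * Cout >= kFloatThreshold;
  if (pointwise) {
    const R_xlen_t N = xd.spatial();
    if (use_float) {
      arma::fmat Wf(K, Cout);
      for (R_xlen_t i = 0; i < K * Cout; ++i) Wf.memptr()[i] = (float)w[i];
      arma::fmat GWf;
      if (need_gw) GWf.zeros(K, Cout);
      arma::fmat xf(N, Cin), gyf(N, Cout);
      for (int b = 0; b < xd.B; ++b) {
        const double* xs = x.begin() + (R_xlen_t)b * N * Cin;
        for (R_xlen_t i = 0; i < N * Cin; ++i) xf.memptr()[i] = (float)xs[i];
        const double* gs = gy.begin() + (R_xlen_t)b * N * Cout;
        for (R_xlen_t i = 0; i < N * Cout; ++i) gyf.memptr()[i] = (float)gs[i];
        if (need_gx) {
          arma::fmat gxm = gyf * Wf.t();
          double* gd = gx.begin() + (R_xlen_t)b * N * Cin;
          for (R_xlen_t i = 0; i < N * Cin; ++i) gd[i] = (double)gxm.memptr()[i];
        }
        if (need_gw) GWf += xf.t() * gyf;
        for (int co = 0; co < Cout; ++co) {
          const double* g = gs + (R_xlen_t)co * N;
          double s = 0;
          for (R_xlen_t i = 0; i < N; ++i) s += g[i];
          gbias[co] += s;
        }
      }
      if (need_gw)
        for (R_xlen_t i = 0; i < K * Cout; ++i) gw[i] = (double)GWf.memptr()[i];
    } else {
      for (int b = 0; b < xd.B; ++b) {
        arma::mat xm(const_cast<double*>(x.begin()) + (R_xlen_t)b * N * Cin,
                     N, Cin, false, true);
        arma::mat gym(const_cast<double*>(gy.begin()) + (R_xlen_t)b * N * Cout,
                      N, Cout, false, true);
        if (need_gx) {
          arma::mat gxm(gx.begin() + (R_xlen_t)b * N * Cin, N, Cin, false, true);
          gxm = gym * Wm.t();
        }
        if (need_gw) GW += xm.t() * gym;
        for (int co = 0; co < Cout; ++co) gbias[co] += arma::accu(gym.col(co));
      }
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbias);
  }
  if (use_float)
    conv_bwd_loop<arma::fmat>(x.begin(), xd, w.begin(), gy.begin(),
                              need_gx ? gx.begin() : nullptr,
                              need_gw ? gw.begin() : nullptr, gbias.begin(),
                              kd, kh, kw, Cout, sd, sh, sw, pd, ph, pw,
                              Do, Ho, Wo, need_gx, need_gw, yd.B);
  else
    conv_bwd_loop<arma::mat>(x.begin(), xd, w.begin(), gy.begin(),
                             need_gx ? gx.begin() : nullptr,
                             need_gw ? gw.begin() : nullptr, gbias.begin(),
                             kd, kh, kw, Cout, sd, sh, sw, pd, ph, pw,
                             Do, Ho, Wo, need_gx, need_gw, yd.B);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbias);
}

// Depthwise conv, stride 1, same padding supplied by caller.
// w dim (kd,kh,kw,C).
// [[Rcpp::export(name = ".cpp_dwconv3d_fwd")]]
NumericVector cpp_dwconv3d_fwd(NumericVector x, NumericVector w,
                               Nullable<NumericVector> bias, IntegerVector pad) {
  Dims5 xd = dims5(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("depthwise weight must be 4-d (kd,kh,kw,C)");
  const int kd = wd[0], kh = wd[1], kw = wd[2];
  if (wd[3] != xd.C) stop("depthwise channel mismatch");
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = xd.D + 2 * pd - kd + 1, Ho = xd.H + 2 * ph - kh + 1,
            Wo = xd.W + 2 * pw - kw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("depthwise output extent < 1");
  const R_xlen_t plane = (R_xlen_t)xd.D * xd.H, chan = plane * xd.W;
  const R_xlen_t oplane = (R_xlen_t)Do * Ho, ochan = oplane * Wo;
  NumericVector y(ochan * xd.C * xd.B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, xd.C, xd.B);
  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bptr = bv.begin(); }
  const R_xlen_t kvol = (R_xlen_t)kd * kh * kw;
  for (int b = 0; b < xd.B; ++b)
    for (int c = 0; c < xd.C; ++c) {
      const double* xc = x.begin() + ((R_xlen_t)b * xd.C + c) * chan;
      double* yc = y.begin() + ((R_xlen_t)b * xd.C + c) * ochan;
      const double binit = bptr ? bptr[c] : 0.0;
      std::fill(yc, yc + ochan, binit);
      const double* wc = w.begin() + kvol * c;
      for (int zw = 0; zw < kw; ++zw)
        for (int zh = 0; zh < kh; ++zh)
          for (int zd = 0; zd < kd; ++zd) {
            const double wv = wc[zd + kd * (zh + kh * zw)];
            if (wv == 0.0) continue;
            const int wlo = std::max(0, pw - zw),
                      whi = std::min(Wo, xd.W + pw - zw);
            const int hlo = std::max(0, ph - zh),
                      hhi = std::min(Ho, xd.H + ph - zh);
            const int dlo = std::max(0, pd - zd),
                      dhi = std::min(Do, xd.D + pd - zd);
            if (kd == 1 && pd == 0) {
              // in-plane kernel: (d,h) fuse into one contiguous run
              const R_xlen_t run = (R_xlen_t)(hhi - hlo) * Do;
              for (int wo = wlo; wo < whi; ++wo) {
                const int wi = wo + zw - pw;
                const double* src = xc + (R_xlen_t)wi * plane +
                                    (R_xlen_t)(hlo + zh - ph) * xd.D;
                double* dst = yc + (R_xlen_t)wo * oplane + (R_xlen_t)hlo * Do;
                for (R_xlen_t i = 0; i < run; ++i) dst[i] += wv * src[i];
              }
              continue;
            }
            for (int wo = wlo; wo < whi; ++wo) {
              const int wi = wo + zw - pw;
              for (int ho = hlo; ho < hhi; ++ho) {
                const int hi = ho + zh - ph;
                const double* src = xc + (R_xlen_t)wi * plane +
                                    (R_xlen_t)hi * xd.D + (dlo + zd - pd);
                double* dst = yc + (R_xlen_t)wo * oplane + (R_xlen_t)ho * Do + dlo;
                const int n = dhi - dlo;
                for (int i = 0; i < n; ++i) dst[i] += wv * src[i];
              }
            }
          }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv3d_bwd")]]
List cpp_dwconv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                      IntegerVector pad, bool need_gx, bool need_gw) {
  Dims5 xd = dims5(x);
  Dims5 yd = dims5(gy);
  IntegerVector wd = w.attr("dim");
  const int kd = wd[0], kh = wd[1], kw = wd[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = yd.D, Ho = yd.H, Wo = yd.W;
  const R_xlen_t plane = (R_xlen_t)xd.D * xd.H, chan = plane * xd.W;
  const R_xlen_t oplane = (R_xlen_t)Do * Ho, ochan = oplane * Wo;
  const R_xlen_t kvol = (R_xlen_t)kd * kh * kw;
  NumericVector gx, gw, gbias(xd.C);
  if (need_gx) { gx = NumericVector(chan * xd.C * xd.B); gx.attr("dim") = x.attr("dim"); }
  if (need_gw) { gw = NumericVector(kvol * xd.C); gw.attr("dim") = w.attr("dim"); }
  for (int b = 0; b < xd.B; ++b)
    for (int c = 0; c < xd.C; ++c) {
      const double* xc = x.begin() + ((R_xlen_t)b * xd.C + c) * chan;
      const double* gyc = gy.begin() + ((R_xlen_t)b * xd.C + c) * ochan;
      double* gxc = need_gx ? gx.begin() + ((R_xlen_t)b * xd.C + c) * chan : nullptr;
      const double* wc = w.begin() + kvol * c;
      double* gwc = need_gw ? gw.begin() + kvol * c : nullptr;
      {
        double s = 0.0;
        for (R_xlen_t i = 0; i < ochan; ++i) s += gyc[i];
        gbias[c] += s;
      }
      for (int zw = 0; zw < kw; ++zw)
        for (int zh = 0; zh < kh; ++zh)
          for (int zd = 0; zd < kd; ++zd) {
            const double wv = wc[zd + kd * (zh + kh * zw)];
            double acc = 0.0;
            const int wlo = std::max(0, pw - zw),
                      whi = std::min(Wo, xd.W + pw - zw);
            const int hlo = std::max(0, ph - zh),
                      hhi = std::min(Ho, xd.H + ph - zh);
            const int dlo = std::max(0, pd - zd),
                      dhi = std::min(Do, xd.D + pd - zd);
            if (kd == 1 && pd == 0) {
              const R_xlen_t run = (R_xlen_t)(hhi - hlo) * Do;
              for (int wo = wlo; wo < whi; ++wo) {
                const int wi = wo + zw - pw;
                const double* src = xc + (R_xlen_t)wi * plane +
                                    (R_xlen_t)(hlo + zh - ph) * xd.D;
                const double* g = gyc + (R_xlen_t)wo * oplane +
                                  (R_xlen_t)hlo * Do;
                if (need_gx && wv != 0.0) {
                  double* dst = gxc + (R_xlen_t)wi * plane +
                                (R_xlen_t)(hlo + zh - ph) * xd.D;
                  for (R_xlen_t i = 0; i < run; ++i) dst[i] += wv * g[i];
                }
                if (need_gw)
                  for (R_xlen_t i = 0; i < run; ++i) acc += src[i] * g[i];
              }
              if (need_gw) gwc[zd + kd * (zh + kh * zw)] += acc;
              continue;
            }
            for (int wo = wlo; wo < whi; ++wo) {
              const int wi = wo + zw - pw;
              for (int ho = hlo; ho < hhi; ++ho) {
                const int hi = ho + zh - ph;
                const double* src = xc + (R_xlen_t)wi * plane +
                                    (R_xlen_t)hi * xd.D + (dlo + zd - pd);
                const double* g = gyc + (R_xlen_t)wo * oplane + (R_xlen_t)ho * Do + dlo;
                const int n = dhi - dlo;
                if (need_gx && wv != 0.0) {
                  double* dst = gxc + (R_xlen_t)wi * plane +
                                (R_xlen_t)hi * xd.D + (dlo + zd - pd);
                  for (int i = 0; i < n; ++i) dst[i] += wv * g[i];
                }
                if (need_gw)
                  for (int i = 0; i < n; ++i) acc += src[i] * g[i];
              }
            }
            if (need_gw) gwc[zd + kd * (zh + kh * zw)] += acc;
          }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbias);
}

// Transposed convolution with kernel == stride (non-overlapping upsampling).
// w dim (Cin, Cout, sd, sh, sw).
// [[Rcpp::export(name = ".cpp_convt3d_fwd")]]
NumericVector cpp_convt3d_fwd(NumericVector x, NumericVector w,
                              Nullable<NumericVector> bias) {
  Dims5 xd = dims5(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("transposed weight must be 5-d (Cin,Cout,sd,sh,sw)");
  const int Cin = wd[0], Cout = wd[1], sd = wd[2], sh = wd[3], sw = wd[4];
  if (Cin != xd.C) stop("transposed conv channel mismatch");
  const int Do = xd.D * sd, Ho = xd.H * sh, Wo = xd.W * sw;
  const R_xlen_t N = xd.spatial();
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(No * Cout * xd.B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, xd.B);
  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bptr = bv.begin(); }
  for (int b = 0; b < xd.B; ++b) {
    arma::mat xm(const_cast<double*>(x.begin()) + (R_xlen_t)b * N * Cin,
                 N, Cin, false, true);
    if (bptr) {
      for (int co = 0; co < Cout; ++co) {
        double* dst = y.begin() + (R_xlen_t)b * No * Cout + (R_xlen_t)co * No;
        std::fill(dst, dst + No, bptr[co]);
      }
    }
    for (int zw = 0; zw < sw; ++zw)
      for (int zh = 0; zh < sh; ++zh)
        for (int zd = 0; zd < sd; ++zd) {
          const R_xlen_t zidx = (R_xlen_t)Cin * Cout * (zd + sd * (zh + sh * zw));
          arma::mat Wz(const_cast<double*>(w.begin()) + zidx, Cin, Cout, false, true);
          arma::mat yz = xm * Wz; // N x Cout
          for (int co = 0; co < Cout; ++co) {
            const double* src = yz.colptr(co);
            double* yc = y.begin() + (R_xlen_t)b * No * Cout + (R_xlen_t)co * No;
            R_xlen_t n = 0;
            for (int wI = 0; wI < xd.W; ++wI) {
              const int wo = wI * sw + zw;
              for (int hI = 0; hI < xd.H; ++hI) {
                const int ho = hI * sh + zh;
                double* base = yc + (R_xlen_t)wo * Do * Ho + (R_xlen_t)ho * Do + zd;
                for (int dI = 0; dI < xd.D; ++dI)
                  base[(R_xlen_t)dI * sd] += src[n++];
              }
            }
          }
        }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_convt3d_bwd")]]
List cpp_convt3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                     bool need_gx, bool need_gw) {
  Dims5 xd = dims5(x);
  Dims5 yd = dims5(gy);
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[0], Cout = wd[1], sd = wd[2], sh = wd[3], sw = wd[4];
  const int Do = yd.D, Ho = yd.H, Wo = yd.W;
  const R_xlen_t N = xd.spatial();
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  NumericVector gx, gw, gbias(Cout);
  if (need_gx) { gx = NumericVector(N * Cin * xd.B); gx.attr("dim") = x.attr("dim"); }
  if (need_gw) { gw = NumericVector((R_xlen_t)Cin * Cout * sd * sh * sw); gw.attr("dim") = w.attr("dim"); }
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (int b = 0; b < yd.B; ++b) {
      const double* g = gy.begin() + (R_xlen_t)b * No * Cout + (R_xlen_t)co * No;
      for (R_xlen_t i = 0; i < No; ++i) s += g[i];
    }
    gbias[co] = s;
  }
  for (int b = 0; b < xd.B; ++b) {
    arma::mat xm(const_cast<double*>(x.begin()) + (R_xlen_t)b * N * Cin,
                 N, Cin, false, true);
    arma::mat gxm(need_gx ? gx.begin() + (R_xlen_t)b * N * Cin : nullptr,
                  need_gx ? N : 0, need_gx ? Cin : 0, false, true);
    for (int zw = 0; zw < sw; ++zw)
      for (int zh = 0; zh < sh; ++zh)
        for (int zd = 0; zd < sd; ++zd) {
          arma::mat gyz(N, Cout);
          for (int co = 0; co < Cout; ++co) {
            const double* yc = gy.begin() + (R_xlen_t)b * No * Cout + (R_xlen_t)co * No;
            double* dst = gyz.colptr(co);
            R_xlen_t n = 0;
            for (int wI = 0; wI < xd.W; ++wI) {
              const int wo = wI * sw + zw;
              for (int hI = 0; hI < xd.H; ++hI) {
                const int ho = hI * sh + zh;
                const double* base = yc + (R_xlen_t)wo * Do * Ho +
                                     (R_xlen_t)ho * Do + zd;
                for (int dI = 0; dI < xd.D; ++dI)
                  dst[n++] = base[(R_xlen_t)dI * sd];
              }
            }
          }
          const R_xlen_t zidx = (R_xlen_t)Cin * Cout * (zd + sd * (zh + sh * zw));
          arma::mat Wz(const_cast<double*>(w.begin()) + zidx, Cin, Cout, false, true);
          if (need_gx) gxm += gyz * Wz.t();
          if (need_gw) {
            arma::mat GWz(gw.begin() + zidx, Cin, Cout, false, true);
            GWz += xm.t() * gyz;
          }
        }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbias);
}

// Instance normalisation with learned affine, per (channel, batch) slice.
// [[Rcpp::export(name = ".cpp_instnorm_fwd")]]
List cpp_instnorm_fwd(NumericVector x, NumericVector gamma,
                      NumericVector beta, double eps) {
  Dims5 xd = dims5(x);
  const R_xlen_t N = xd.spatial();
  const int CB = xd.C * xd.B;
  NumericVector y(N * CB);
  y.attr("dim") = x.attr("dim");
  NumericVector mu(CB), istd(CB);
  for (int cb = 0; cb < CB; ++cb) {
    const int c = cb % xd.C;
    const double* xs = x.begin() + (R_xlen_t)cb * N;
    double* ys = y.begin() + (R_xlen_t)cb * N;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < N; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    const double m = s / N;
    double v = s2 / N - m * m;
    if (v < 0) v = 0;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[cb] = m; istd[cb] = is;
    const double a = gamma[c] * is, b0 = beta[c] - a * m;
    for (R_xlen_t i = 0; i < N; ++i) ys[i] = a * xs[i] + b0;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export(name = ".cpp_instnorm_bwd")]]
List cpp_instnorm_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
                      NumericVector mu, NumericVector istd, bool need_gx) {
  Dims5 xd = dims5(x);
  const R_xlen_t N = xd.spatial();
  const int CB = xd.C * xd.B;
  NumericVector gx, ggamma(xd.C), gbeta(xd.C);
  if (need_gx) { gx = NumericVector(N * CB); gx.attr("dim") = x.attr("dim"); }
  for (int cb = 0; cb < CB; ++cb) {
    const int c = cb % xd.C;
    const double* xs = x.begin() + (R_xlen_t)cb * N;
    const double* gs = gy.begin() + (R_xlen_t)cb * N;
    const double m = mu[cb], is = istd[cb];
    double sg = 0, sgx = 0;
    for (R_xlen_t i = 0; i < N; ++i) {
      const double xh = (xs[i] - m) * is;
      sg += gs[i];
      sgx += gs[i] * xh;
    }
    ggamma[c] += sgx;
    gbeta[c] += sg;
    if (need_gx) {
      double* gd = gx.begin() + (R_xlen_t)cb * N;
      const double mg = sg / N, mgx = sgx / N, a = gamma[c] * is;
      for (R_xlen_t i = 0; i < N; ++i) {
        const double xh = (xs[i] - m) * is;
        gd[i] = a * (gs[i] - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Leaky ReLU forward / backward (elementwise, avoids R-level ifelse)
// [[Rcpp::export(name = ".cpp_leaky_relu_fwd")]]
NumericVector cpp_leaky_relu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export(name = ".cpp_leaky_relu_bwd")]]
NumericVector cpp_leaky_relu_bwd(NumericVector x, NumericVector gy,
                                 double slope) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    gx[i] = x[i] > 0 ? gy[i] : slope * gy[i];
  return gx;
}

// ---- geometry -------------------------------------------------------------

// Resample a (D,H,W) scalar array to out_shape.  Centre-aligned mapping:
// x_in = (i_out + 0.5) * n_in/n_out - 0.5.  method: 0 = trilinear, 1 = nearest.
// [[Rcpp::export(name = ".cpp_resample3d")]]
NumericVector cpp_resample3d(NumericVector src, IntegerVector out_shape, int method) {
  IntegerVector sd = src.attr("dim");
  if (sd.size() != 3) stop("expected a 3-d array");
  const int D = sd[0], H = sd[1], W = sd[2];
  const int Do = out_shape[0], Ho = out_shape[1], Wo = out_shape[2];
  if (Do < 1 || Ho < 1 || Wo < 1) stop("output shape must be positive");
  NumericVector out((R_xlen_t)Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  const double rd = (double)D / Do, rh = (double)H / Ho, rw = (double)W / Wo;
  const double* s = src.begin();
  double* o = out.begin();
  R_xlen_t n = 0;
  for (int w = 0; w < Wo; ++w) {
    const double xw = (w + 0.5) * rw - 0.5;
    for (int h = 0; h < Ho; ++h) {
      const double xh = (h + 0.5) * rh - 0.5;
      for (int d = 0; d < Do; ++d, ++n) {
        const double xd_ = (d + 0.5) * rd - 0.5;
        if (method == 1) {
          const int di = std::min(D - 1, std::max(0, (int)std::lround(xd_)));
          const int hi = std::min(H - 1, std::max(0, (int)std::lround(xh)));
          const int wi = std::min(W - 1, std::max(0, (int)std::lround(xw)));
          o[n] = s[di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi)];
        } else {
          const int d0 = (int)std::floor(xd_), h0 = (int)std::floor(xh),
                    w0 = (int)std::floor(xw);
          const double fd = xd_ - d0, fh = xh - h0, fw = xw - w0;
          double acc = 0.0;
          for (int dw = 0; dw <= 1; ++dw) {
            const int wi = std::min(W - 1, std::max(0, w0 + dw));
            const double ww = dw ? fw : 1 - fw;
            for (int dh = 0; dh <= 1; ++dh) {
              const int hi = std::min(H - 1, std::max(0, h0 + dh));
              const double wh = dh ? fh : 1 - fh;
              for (int dd = 0; dd <= 1; ++dd) {
                const int di = std::min(D - 1, std::max(0, d0 + dd));
                const double wd_ = dd ? fd : 1 - fd;
                acc += ww * wh * wd_ * s[di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi)];
              }
            }
          }
          o[n] = acc;
        }
      }
    }
  }
  return out;
}

// In-plane (H,W) warp of a (D,H,W) array about its centre:
// source coords = A %*% (p - c) + c + t + disp(p).  A is 2x2 row-major
// (a11,a12,a21,a22) acting on (h,w); disp arrays optional, same shape.
// method: 0 = bilinear, 1 = nearest.  Outside -> fill.
// [[Rcpp::export(name = ".cpp_warp_inplane")]]
NumericVector cpp_warp_inplane(NumericVector src, NumericVector A,
                               NumericVector t,
                               Nullable<NumericVector> disp_h,
                               Nullable<NumericVector> disp_w,
                               int method, double fill) {
  IntegerVector sd = src.attr("dim");
  const int D = sd[0], H = sd[1], W = sd[2];
  NumericVector out((R_xlen_t)D * H * W);
  out.attr("dim") = sd;
  const double ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  const double a11 = A[0], a12 = A[1], a21 = A[2], a22 = A[3];
  const double th = t[0], tw = t[1];
  const double* dh_ = disp_h.isNotNull() ? NumericVector(disp_h.get()).begin() : nullptr;
  // note: keep the NumericVector alive
  NumericVector dhv, dwv;
  const double* dhp = nullptr; const double* dwp = nullptr;
  if (disp_h.isNotNull()) { dhv = disp_h.get(); dhp = dhv.begin(); }
  if (disp_w.isNotNull()) { dwv = disp_w.get(); dwp = dwv.begin(); }
  (void)dh_;
  const double* s = src.begin();
  double* o = out.begin();
  R_xlen_t n = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++n) {
        const double hc = h - ch, wc = w - cw;
        double sh_ = a11 * hc + a12 * wc + ch + th;
        double sw_ = a21 * hc + a22 * wc + cw + tw;
        if (dhp) sh_ += dhp[n];
        if (dwp) sw_ += dwp[n];
        if (method == 1) {
          const int hi = (int)std::lround(sh_), wi = (int)std::lround(sw_);
          o[n] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                     ? s[d + (R_xlen_t)D * (hi + (R_xlen_t)H * wi)] : fill;
        } else {
          const int h0 = (int)std::floor(sh_), w0 = (int)std::floor(sw_);
          if (h0 < -1 || h0 > H - 1 || w0 < -1 || w0 > W - 1) { o[n] = fill; continue; }
          const double fh = sh_ - h0, fw = sw_ - w0;
          double acc = 0.0;
          for (int dw2 = 0; dw2 <= 1; ++dw2)
            for (int dh2 = 0; dh2 <= 1; ++dh2) {
              const int hi = h0 + dh2, wi = w0 + dw2;
              const double wt = (dh2 ? fh : 1 - fh) * (dw2 ? fw : 1 - fw);
              const double v = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                                   ? s[d + (R_xlen_t)D * (hi + (R_xlen_t)H * wi)] : fill;
              acc += wt * v;
            }
          o[n] = acc;
        }
      }
  return out;
}

// Boundary voxels of a binary mask (6-connectivity; volume edge counts as
// background).  Returns an n x 3 matrix of 0-based (d,h,w) indices.
// [[Rcpp::export(name = ".cpp_boundary_voxels")]]
IntegerMatrix cpp_boundary_voxels(LogicalVector mask) {
  IntegerVector sd = mask.attr("dim");
  if (sd.size() != 3) stop("expected a 3-d mask");
  const int D = sd[0], H = sd[1], W = sd[2];
  const int* m = LOGICAL(mask);
  std::vector<int> out;
  auto at = [&](int d, int h, int w) -> int {
    if (d < 0 || d >= D || h < 0 || h >= H || w < 0 || w >= W) return 0;
    return m[d + (R_xlen_t)D * (h + (R_xlen_t)H * w)] == 1;
  };
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        if (!at(d, h, w)) continue;
        if (!at(d - 1, h, w) || !at(d + 1, h, w) || !at(d, h - 1, w) ||
            !at(d, h + 1, w) || !at(d, h, w - 1) || !at(d, h, w + 1)) {
          out.push_back(d); out.push_back(h); out.push_back(w);
        }
      }
  const int n = out.size() / 3;
  IntegerMatrix res(n, 3);
  for (int i = 0; i < n; ++i) {
    res(i, 0) = out[3 * i]; res(i, 1) = out[3 * i + 1]; res(i, 2) = out[3 * i + 2];
  }
  return res;
}

// Directed surface distances: for every point of A, the minimum Euclidean
// distance (under physical spacing) to any point of B.  Brute force.
// [[Rcpp::export(name = ".cpp_directed_dists")]]
NumericVector cpp_directed_dists(IntegerMatrix A, IntegerMatrix B,
                                 NumericVector spacing) {
  const int n = A.nrow(), mN = B.nrow();
  if (mN == 0) stop("empty reference surface");
  NumericVector out(n);
  const double sd_ = spacing[0], sh = spacing[1], sw = spacing[2];
  std::vector<double> bd(mN), bh(mN), bw(mN);
  for (int j = 0; j < mN; ++j) {
    bd[j] = B(j, 0) * sd_; bh[j] = B(j, 1) * sh; bw[j] = B(j, 2) * sw;
  }
  for (int i = 0; i < n; ++i) {
    const double ad = A(i, 0) * sd_, ah = A(i, 1) * sh, aw = A(i, 2) * sw;
    double best = R_PosInf;
    for (int j = 0; j < mN; ++j) {
      const double dd = ad - bd[j], dh2 = ah - bh[j], dw2 = aw - bw[j];
      const double dist2 = dd * dd + dh2 * dh2 + dw2 * dw2;
      if (dist2 < best) best = dist2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
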