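// Low-level 3D conv / max-pool kernels for the volume encoders.
// Arrays are R column-major, laid out (D, H, W, C): depth index fastest.
// Valid convolution only (stride 1, no padding); pooling is kernel 2,
// stride 2, floor semantics. These are the only hot loops in the
// package; everything else stays in R.
#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int d, int h, int w, int c,
                            int D, int H, int W) {
  return d + (R_xlen_t)D * (h + (R_xlen_t)H * (w + (R_xlen_t)W * c));
}

// x: (D, H, W, Cin); w: (k, k, k, Cin, Cout); b: length Cout
// returns (D-k+1, H-k+1, W-k+1, Cout)
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int Do = D - k + 1, Ho = H - k + 1, Wo = W - k + 1;
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("conv3d_fwd: input spatial dims smaller than kernel");
  NumericVector y(Do * (R_xlen_t)Ho * Wo * Cout);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();

  for (int co = 0; co < Cout; ++co) {
    // bias fill
    R_xlen_t base = (R_xlen_t)Do * Ho * Wo * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)Do * Ho * Wo; ++i) py[base + i] = pb[co];
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          for (int kd = 0; kd < k; ++kd) {
            const double wv =
              pw[kd + (R_xlen_t)k * (kh + (R_xlen_t)k * (kw + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)))];
            if (wv == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo)
              for (int ho = 0; ho < Ho; ++ho) {
                const double *xs = px + idx4(kd, ho + kh, wo + kw, ci, D, H, W);
                double *ys = py + idx4(0, ho, wo, co, Do, Ho, Wo);
                for (int dd = 0; dd < Do; ++dd) ys[dd] += wv * xs[dd];
              }
          }
  }
  return y;
}

// gradients of conv3d_fwd; gy has the output's dims
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int Do = yd[0], Ho = yd[1], Wo = yd[2];

  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();

  for (int co = 0; co < Cout; ++co) {
    // bias gradient: sum of gy over spatial
    double s = 0.0;
    R_xlen_t base = (R_xlen_t)Do * Ho * Wo * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)Do * Ho * Wo; ++i) s += pg[base + i];
    pgb[co] = s;
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          for (int kd = 0; kd < k; ++kd) {
            const R_xlen_t wi =
              kd + (R_xlen_t)k * (kh + (R_xlen_t)k * (kw + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)));
            const double wv = pw[wi];
            double acc = 0.0;
            for (int wo = 0; wo < Wo; ++wo)
              for (int ho = 0; ho < Ho; ++ho) {
                const double *xs = px + idx4(kd, ho + kh, wo + kw, ci, D, H, W);
                double *gxs = pgx + idx4(kd, ho + kh, wo + kw, ci, D, H, W);
                const double *gs = pg + idx4(0, ho, wo, co, Do, Ho, Wo);
                for (int dd = 0; dd < Do; ++dd) {
                  acc += gs[dd] * xs[dd];
                  gxs[dd] += wv * gs[dd];
                }
              }
            pgw[wi] += acc;
          }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// max pool kernel 2 stride 2, floor semantics; also returns 1-based
// linear argmax indices into x for the backward pass
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("maxpool3d_fwd: dimension collapses to zero");
  NumericVector y((R_xlen_t)Do * Ho * Wo * C);
  IntegerVector am(y.size());
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  am.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = am.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int dd = 0; dd < Do; ++dd, ++o) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                R_xlen_t i = idx4(2 * dd + kd, 2 * ho + kh, 2 * wo + kw, c, D, H, W);
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          py[o] = best;
          pa[o] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// scatter gy back through the recorded argmax positions
// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, IntegerVector argmax, IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double *pgx = gx.begin();
  const double *pg = gy.begin();
  const int *pa = argmax.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pa[i] - 1] += pg[i];
  return gx;
}
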