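#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are stored as R arrays [h, w, c] (column-major), weights as
// [kh, kw, cin, cout]. All kernels are single-threaded and deterministic.

static inline int idx3(int i, int j, int k, int h, int w) {
  return i + h * (j + w * k);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, int h, int w, int cin,
                             NumericVector wgt, int kh, int kw, int cout,
                             NumericVector bias, int stride, int pad) {
  int ho = (h + 2 * pad - kh) / stride + 1;
  int wo = (w + 2 * pad - kw) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * cout);
  const double *px = x.begin(), *pw = wgt.begin(), *pb = bias.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    for (int oj = 0; oj < wo; ++oj) {
      for (int oi = 0; oi < ho; ++oi) {
        double acc = pb[co];
        int ibase = oi * stride - pad, jbase = oj * stride - pad;
        for (int ci = 0; ci < cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int jj = jbase + kj;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int ii = ibase + ki;
              if (ii < 0 || ii >= h) continue;
              acc += px[idx3(ii, jj, ci, h, w)] *
                     pw[ki + kh * (kj + kw * (ci + cin * co))];
            }
          }
        }
        py[idx3(oi, oj, co, ho, wo)] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, int h, int w, int cin,
                    NumericVector wgt, int kh, int kw, int cout,
                    NumericVector gout, int stride, int pad, bool need_gx) {
  int ho = (h + 2 * pad - kh) / stride + 1;
  int wo = (w + 2 * pad - kw) / stride + 1;
  NumericVector gx(need_gx ? static_cast<R_xlen_t>(h) * w * cin : 0);
  NumericVector gw(static_cast<R_xlen_t>(kh) * kw * cin * cout);
  NumericVector gb(cout);
  const double *px = x.begin(), *pw = wgt.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < cout; ++co) {
    for (int oj = 0; oj < wo; ++oj) {
      for (int oi = 0; oi < ho; ++oi) {
        double g = pg[idx3(oi, oj, co, ho, wo)];
        if (g == 0.0) continue;
        pgb[co] += g;
        int ibase = oi * stride - pad, jbase = oj * stride - pad;
        for (int ci = 0; ci < cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int jj = jbase + kj;
            if (jj < 0 || jj >= w) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int ii = ibase + ki;
              if (ii < 0 || ii >= h) continue;
              int xi = idx3(ii, jj, ci, h, w);
              int wi = ki + kh * (kj + kw * (ci + cin * co));
              pgw[wi] += g * px[xi];
              if (need_gx) pgx[xi] += g * pw[wi];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; h and w must be even (validated in R).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, int h, int w, int c) {
  int ho = h / 2, wo = w / 2;
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * c);
  IntegerVector arg(static_cast<R_xlen_t>(ho) * wo * c); // 1-based into x
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int k = 0; k < c; ++k) {
    for (int oj = 0; oj < wo; ++oj) {
      for (int oi = 0; oi < ho; ++oi) {
        double best = -1e300;
        int besti = -1;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            int xi = idx3(2 * oi + di, 2 * oj + dj, k, h, w);
            if (px[xi] > best) { best = px[xi]; besti = xi; }
          }
        }
        int yi = idx3(oi, oj, k, ho, wo);
        py[yi] = best;
        pa[yi] = besti + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// Bilinear resize [h,w,c] -> [ho,wo,c] with half-pixel centre mapping.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int h, int w, int c,
                                      int ho, int wo) {
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * c);
  const double *px = x.begin();
  double *py = y.begin();
  double si = (double)h / ho, sj = (double)w / wo;
  for (int oj = 0; oj < wo; ++oj) {
    double srcj = (oj + 0.5) * sj - 0.5;
    int j0 = (int)std::floor(srcj);
    double fj = srcj - j0;
    if (j0 < 0) { j0 = 0; fj = 0.0; }
    int j1 = j0 + 1 < w ? j0 + 1 : w - 1;
    if (j0 > w - 1) { j0 = w - 1; fj = 0.0; }
    for (int oi = 0; oi < ho; ++oi) {
      double srci = (oi + 0.5) * si - 0.5;
      int i0 = (int)std::floor(srci);
      double fi = srci - i0;
      if (i0 < 0) { i0 = 0; fi = 0.0; }
      int i1 = i0 + 1 < h ? i0 + 1 : h - 1;
      if (i0 > h - 1) { i0 = h - 1; fi = 0.0; }
      for (int k = 0; k < c; ++k) {
        double v00 = px[idx3(i0, j0, k, h, w)], v10 = px[idx3(i1, j0, k, h, w)];
        double v01 = px[idx3(i0, j1, k, h, w)], v11 = px[idx3(i1, j1, k, h, w)];
        py[idx3(oi, oj, k, ho, wo)] =
          (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
          (1 - fi) * fj * v01 + fi * fj * v11;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gout, int h, int w, int c,
                                      int ho, int wo) {
  NumericVector gx(static_cast<R_xlen_t>(h) * w * c);
  const double *pg = gout.begin();
  double *pgx = gx.begin();
  double si = (double)h / ho, sj = (double)w / wo;
  for (int oj = 0; oj < wo; ++oj) {
    double srcj = (oj + 0.5) * sj - 0.5;
    int j0 = (int)std::floor(srcj);
    double fj = srcj - j0;
    if (j0 < 0) { j0 = 0; fj = 0.0; }
    int j1 = j0 + 1 < w ? j0 + 1 : w - 1;
    if (j0 > w - 1) { j0 = w - 1; fj = 0.0; }
    for (int oi = 0; oi < ho; ++oi) {
      double srci = (oi + 0.5) * si - 0.5;
      int i0 = (int)std::floor(srci);
      double fi = srci - i0;
      if (i0 < 0) { i0 = 0; fi = 0.0; }
      int i1 = i0 + 1 < h ? i0 + 1 : h - 1;
      if (i0 > h - 1) { i0 = h - 1; fi = 0.0; }
      for (int k = 0; k < c; ++k) {
        double g = pg[idx3(oi, oj, k, ho, wo)];
        pgx[idx3(i0, j0, k, h, w)] += (1 - fi) * (1 - fj) * g;
        pgx[idx3(i1, j0, k, h, w)] += fi * (1 - fj) * g;
        pgx[idx3(i0, j1, k, h, w)] += (1 - fi) * fj * g;
        pgx[idx3(i1, j1, k, h, w)] += fi * fj * g;
      }
    }
  }
  return gx;
}
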