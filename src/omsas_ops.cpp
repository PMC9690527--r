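// Hot kernels of the CNN engine: depthwise 3x3 convolution, per-position
// layer normalization and 2x2 max pooling, forward and backward. Arrays
// are column-major (h, w, c) as produced by R; zero padding at the border.
// Raw-pointer access throughout; the convolution interior is branch-free.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".dw_fwd_cpp")]]
NumericVector dw_fwd_cpp(const NumericVector& x, const NumericVector& K,
                         const NumericVector& b, int h, int w, int c) {
  NumericVector y(no_init(x.size()));
  const double* xp0 = REAL(x);
  const double* Kp = REAL(K);
  const double* bp = REAL(b);
  double* yp0 = REAL(y);
  const R_xlen_t plane = (R_xlen_t)h * w;
  for (int ch = 0; ch < c; ++ch) {
    const double* xp = xp0 + plane * ch;
    double* yp = yp0 + plane * ch;
    const double* kp = Kp + 9 * ch;
    const double bias = bp[ch];
    for (int j = 0; j < w; ++j) {
      const bool jlo = j > 0, jhi = j < w - 1;
      const double* xm = xp + (R_xlen_t)(j - 1) * h;  // column j-1
      const double* x0 = xp + (R_xlen_t)j * h;        // column j
      const double* xq = xp + (R_xlen_t)(j + 1) * h;  // column j+1
      double* yc = yp + (R_xlen_t)j * h;
      for (int i = 0; i < h; ++i) {
        const bool ilo = i > 0, ihi = i < h - 1;
        double acc = bias;
        if (jlo) {
          if (ilo) acc += kp[0] * xm[i - 1];
          acc += kp[1] * xm[i];
          if (ihi) acc += kp[2] * xm[i + 1];
        }
        if (ilo) acc += kp[3] * x0[i - 1];
        acc += kp[4] * x0[i];
        if (ihi) acc += kp[5] * x0[i + 1];
        if (jhi) {
          if (ilo) acc += kp[6] * xq[i - 1];
          acc += kp[7] * xq[i];
          if (ihi) acc += kp[8] * xq[i + 1];
        }
        yc[i] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(h, w, c);
  return y;
}

// [[Rcpp::export(name = ".dw_bwd_cpp")]]
List dw_bwd_cpp(const NumericVector& x, const NumericVector& K,
                const NumericVector& dy, int h, int w, int c) {
  NumericVector dx(x.size());            // zero-initialized
  NumericVector dK(9 * c);
  NumericVector db(c);
  const double* xp0 = REAL(x);
  const double* Kp = REAL(K);
  const double* gp0 = REAL(dy);
  double* dxp0 = REAL(dx);
  double* dKp0 = REAL(dK);
  double* dbp = REAL(db);
  const R_xlen_t plane = (R_xlen_t)h * w;
  for (int ch = 0; ch < c; ++ch) {
    const double* xp = xp0 + plane * ch;
    const double* gp = gp0 + plane * ch;
    double* dxp = dxp0 + plane * ch;
    const double* kp = Kp + 9 * ch;
    double* dkp = dKp0 + 9 * ch;
    double bacc = 0.0;
    for (int j = 0; j < w; ++j) {
      const bool jlo = j > 0, jhi = j < w - 1;
      const R_xlen_t cm = (R_xlen_t)(j - 1) * h, c0 = (R_xlen_t)j * h,
                     cq = (R_xlen_t)(j + 1) * h;
      for (int i = 0; i < h; ++i) {
        const double g = gp[c0 + i];
        bacc += g;
        const bool ilo = i > 0, ihi = i < h - 1;
        if (jlo) {
          if (ilo) { dkp[0] += xp[cm + i - 1] * g; dxp[cm + i - 1] += kp[0] * g; }
          dkp[1] += xp[cm + i] * g; dxp[cm + i] += kp[1] * g;
          if (ihi) { dkp[2] += xp[cm + i + 1] * g; dxp[cm + i + 1] += kp[2] * g; }
        }
        if (ilo) { dkp[3] += xp[c0 + i - 1] * g; dxp[c0 + i - 1] += kp[3] * g; }
        dkp[4] += xp[c0 + i] * g; dxp[c0 + i] += kp[4] * g;
        if (ihi) { dkp[5] += xp[c0 + i + 1] * g; dxp[c0 + i + 1] += kp[5] * g; }
        if (jhi) {
          if (ilo) { dkp[6] += xp[cq + i - 1] * g; dxp[cq + i - 1] += kp[6] * g; }
          dkp[7] += xp[cq + i] * g; dxp[cq + i] += kp[7] * g;
          if (ihi) { dkp[8] += xp[cq + i + 1] * g; dxp[cq + i + 1] += kp[8] * g; }
        }
      }
    }
    dbp[ch] = bacc;
  }
  dx.attr("dim") = IntegerVector::create(h, w, c);
  dK.attr("dim") = IntegerVector::create(3, 3, c);
  return List::create(_["dx"] = dx, _["dK"] = dK, _["db"] = db);
}

// layer norm across channels at each spatial position
// [[Rcpp::export(name = ".ln_fwd_cpp")]]
List ln_fwd_cpp(const NumericVector& x, const NumericVector& g,
                const NumericVector& b, int hw, int c, double eps) {
  NumericVector y(no_init(x.size()));
  NumericVector xhat(no_init(x.size()));
  NumericVector inv(no_init(hw));
  const double* xp = REAL(x);
  const double* gw = REAL(g);
  const double* bo = REAL(b);
  double* yp = REAL(y);
  double* xh = REAL(xhat);
  double* ip = REAL(inv);
  for (int p = 0; p < hw; ++p) {
    double mu = 0.0;
    for (int ch = 0; ch < c; ++ch) mu += xp[p + (R_xlen_t)hw * ch];
    mu /= c;
    double v = 0.0;
    for (int ch = 0; ch < c; ++ch) {
      const double d = xp[p + (R_xlen_t)hw * ch] - mu;
      v += d * d;
    }
    const double iv = 1.0 / std::sqrt(v / c + eps);
    ip[p] = iv;
    for (int ch = 0; ch < c; ++ch) {
      const R_xlen_t k = p + (R_xlen_t)hw * ch;
      const double z = (xp[k] - mu) * iv;
      xh[k] = z;
      yp[k] = z * gw[ch] + bo[ch];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = ".ln_bwd_cpp")]]
List ln_bwd_cpp(const NumericVector& dy, const NumericVector& xhat,
                const NumericVector& inv, const NumericVector& g,
                int hw, int c) {
  NumericVector dx(no_init(dy.size()));
  NumericVector dg(c);
  NumericVector db(c);
  const double* dyp = REAL(dy);
  const double* xh = REAL(xhat);
  const double* ip = REAL(inv);
  const double* gw = REAL(g);
  double* dxp = REAL(dx);
  double* dgp = REAL(dg);
  double* dbp = REAL(db);
  for (int p = 0; p < hw; ++p) {
    double m1 = 0.0, m2 = 0.0;
    for (int ch = 0; ch < c; ++ch) {
      const R_xlen_t k = p + (R_xlen_t)hw * ch;
      const double d = dyp[k];
      dgp[ch] += d * xh[k];
      dbp[ch] += d;
      const double dxhat = d * gw[ch];
      m1 += dxhat;
      m2 += dxhat * xh[k];
    }
    m1 /= c;
    m2 /= c;
    for (int ch = 0; ch < c; ++ch) {
      const R_xlen_t k = p + (R_xlen_t)hw * ch;
      dxp[k] = ip[p] * (dyp[k] * gw[ch] - m1 - xh[k] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// [[Rcpp::export(name = ".pool2_fwd_cpp")]]
List pool2_fwd_cpp(const NumericVector& x, int h, int w, int c) {
  const int ho = h / 2, wo = w / 2;
  NumericVector y(no_init((R_xlen_t)ho * wo * c));
  IntegerVector idx(no_init((R_xlen_t)ho * wo * c));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ixp = INTEGER(idx);
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t xoff = (R_xlen_t)h * w * ch;
    const R_xlen_t yoff = (R_xlen_t)ho * wo * ch;
    for (int j = 0; j < wo; ++j) {
      const R_xlen_t c0 = xoff + (R_xlen_t)(2 * j) * h;
      const R_xlen_t c1 = c0 + h;
      for (int i = 0; i < ho; ++i) {
        const int i0 = 2 * i;
        // candidates in fixed order: (0,0), (1,0), (0,1), (1,1)
        R_xlen_t cand[4] = {c0 + i0, c0 + i0 + 1, c1 + i0, c1 + i0 + 1};
        R_xlen_t best = cand[0];
        double bv = xp[cand[0]];
        for (int k = 1; k < 4; ++k)
          if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
        const R_xlen_t o = yoff + i + (R_xlen_t)ho * j;
        yp[o] = bv;
        ixp[o] = (int)best;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ho, wo, c);
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["in_dim"] = IntegerVector::create(h, w, c));
}

// [[Rcpp::export(name = ".pool2_bwd_cpp")]]
NumericVector pool2_bwd_cpp(const NumericVector& dy, const IntegerVector& idx,
                            const IntegerVector& in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2]);
  const double* dyp = REAL(dy);
  const int* ixp = INTEGER(idx);
  double* dxp = REAL(dx);
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) dxp[ixp[k]] += dyp[k];
  dx.attr("dim") = in_dim;
  return dx;
}
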