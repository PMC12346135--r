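// Dense 2-D convolution arithmetic for channel-last (H, W, C, N) arrays.
//
// Convolutions are stride-1, odd square kernels, zero "same" padding, with
// channel groups (groups == C gives a depth-wise convolution).  Forward and
// backward passes both go through an im2col buffer and a BLAS gemm; the
// buffer is built in column chunks so peak memory stays bounded even for
// 512x512 feature maps with 7x7 kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int IM2COL_CHUNK = 16384;

// Fill M (rows = k*k*cing, cols = p1-p0) with patches of image n, group g.
static void im2col_chunk(const double* x, int H, int W, int cin, int n,
                         int k, int pad, int ci0, int cing,
                         int p0, int p1, arma::mat& M) {
  const int HW = H * W;
  for (int p = p0; p < p1; ++p) {
    const int h = p % H, w = p / H;
    double* col = M.colptr(p - p0);
    int r = 0;
    for (int ci = 0; ci < cing; ++ci) {
      const double* xc = x + (size_t)HW * (cin * n + ci0 + ci);
      for (int dw = -pad; dw <= pad; ++dw) {
        const int ww = w + dw;
        if (ww < 0 || ww >= W) {
          for (int dh = -pad; dh <= pad; ++dh) col[r++] = 0.0;
        } else {
          const double* xcol = xc + (size_t)H * ww;
          for (int dh = -pad; dh <= pad; ++dh) {
            const int hh = h + dh;
            col[r++] = (hh < 0 || hh >= H) ? 0.0 : xcol[hh];
          }
        }
      }
    }
  }
}

// Note: im2col row order is (dh, dw, ci) fastest-first, matching the
// column-major layout of a weight array with dim (k, k, cing, cout).

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b, int groups) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cing = wd[2], cout = wd[3];
  const int pad = (k - 1) / 2, coutg = cout / groups, rows = k * k * cing;
  const int HW = H * W;
  if (cing * groups != cin) stop("conv2d: input channels do not match weight/groups");
  NumericVector out((size_t)HW * cout * N);
  out.attr("dim") = IntegerVector::create(H, W, cout, N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)rows * coutg * g,
                         rows, coutg, false, true);
      for (int p0 = 0; p0 < HW; p0 += IM2COL_CHUNK) {
        const int p1 = std::min(HW, p0 + IM2COL_CHUNK);
        arma::mat M(rows, p1 - p0);
        im2col_chunk(xp, H, W, cin, n, k, pad, g * cing, cing, p0, p1, M);
        arma::mat O = M.t() * Wg;  // (chunk x coutg)
        for (int co = 0; co < coutg; ++co) {
          double* dst = op + (size_t)HW * (cout * n + g * coutg + co) + p0;
          const double* src = O.colptr(co);
          const double bias = b[g * coutg + co];
          for (int p = 0; p < p1 - p0; ++p) dst[p] = src[p] + bias;
        }
      }
    }
  }
  return out;
}

// Scatter-add of a column buffer back to the input gradient (col2im).
static void col2im_chunk(double* gx, int H, int W, int cin, int n,
                         int k, int pad, int ci0, int cing,
                         int p0, int p1, const arma::mat& M) {
  const int HW = H * W;
  for (int p = p0; p < p1; ++p) {
    const int h = p % H, w = p / H;
    const double* col = M.colptr(p - p0);
    int r = 0;
    for (int ci = 0; ci < cing; ++ci) {
      double* xc = gx + (size_t)HW * (cin * n + ci0 + ci);
      for (int dw = -pad; dw <= pad; ++dw) {
        const int ww = w + dw;
        if (ww < 0 || ww >= W) { r += k; continue; }
        double* xcol = xc + (size_t)H * ww;
        for (int dh = -pad; dh <= pad; ++dh) {
          const int hh = h + dh;
          if (hh >= 0 && hh < H) xcol[hh] += col[r];
          ++r;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& x, const NumericVector& w,
                    const NumericVector& gout, int groups) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cing = wd[2], cout = wd[3];
  const int pad = (k - 1) / 2, coutg = cout / groups, rows = k * k * cing;
  const int HW = H * W;
  NumericVector gx(x.size()), gw(w.size()), gb(cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double* xp = x.begin();
  const double* gop = gout.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)rows * coutg * g,
                         rows, coutg, false, true);
      arma::mat gWg(gw.begin() + (size_t)rows * coutg * g, rows, coutg, false, true);
      for (int p0 = 0; p0 < HW; p0 += IM2COL_CHUNK) {
        const int p1 = std::min(HW, p0 + IM2COL_CHUNK);
        const int nc = p1 - p0;
        arma::mat GO(nc, coutg);
        for (int co = 0; co < coutg; ++co) {
          const double* src = gop + (size_t)HW * (cout * n + g * coutg + co) + p0;
          std::copy(src, src + nc, GO.colptr(co));
          double s = 0.0;
          for (int p = 0; p < nc; ++p) s += src[p];
          gb[g * coutg + co] += s;
        }
        arma::mat M(rows, nc);
        im2col_chunk(xp, H, W, cin, n, k, pad, g * cing, cing, p0, p1, M);
        gWg += M * GO;
        arma::mat GM = Wg * GO.t();  // rows x chunk
        col2im_chunk(gx.begin(), H, W, cin, n, k, pad, g * cing, cing, p0, p1, GM);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, fixed 2x2 kernel and stride 2: doubles H and W.
// Weight dim: (2, 2, cout, cin).
// [[Rcpp::export]]
NumericVector convt2_fwd_cpp(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  IntegerVector wd = w.attr("dim");
  const int cout = wd[2];
  const int Ho = 2 * H, Wo = 2 * W, HWo = Ho * Wo;
  NumericVector out((size_t)HWo * cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      double* oc = op + (size_t)HWo * (cout * n + co);
      for (int p = 0; p < HWo; ++p) oc[p] = b[co];
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = xp + (size_t)H * W * (cin * n + ci);
        const double* wk = wp + 4 * ((size_t)cout * ci + co);  // (dh,dw) block
        for (int wcol = 0; wcol < W; ++wcol)
          for (int h = 0; h < H; ++h) {
            const double v = xc[h + (size_t)H * wcol];
            double* o00 = oc + (size_t)Ho * (2 * wcol) + 2 * h;
            double* o01 = o00 + Ho;
            o00[0] += v * wk[0];
            o00[1] += v * wk[1];
            o01[0] += v * wk[2];
            o01[1] += v * wk[3];
          }
      }
    }
  return out;
}

// [[Rcpp::export]]
List convt2_bwd_cpp(const NumericVector& x, const NumericVector& w,
                    const NumericVector& gout) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], cin = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  IntegerVector wd = w.attr("dim");
  const int cout = wd[2];
  const int Ho = 2 * H, Wo = 2 * W, HWo = Ho * Wo;
  NumericVector gx(x.size()), gw(w.size()), gb(cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gop = gout.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      const double* gc = gop + (size_t)HWo * (cout * n + co);
      double s = 0.0;
      for (int p = 0; p < HWo; ++p) s += gc[p];
      gb[co] += s;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = xp + (size_t)H * W * (cin * n + ci);
        double* gxc = gx.begin() + (size_t)H * W * (cin * n + ci);
        const double* wk = wp + 4 * ((size_t)cout * ci + co);
        double* gwk = gw.begin() + 4 * ((size_t)cout * ci + co);
        for (int wcol = 0; wcol < W; ++wcol)
          for (int h = 0; h < H; ++h) {
            const double v = xc[h + (size_t)H * wcol];
            const double* g00 = gc + (size_t)Ho * (2 * wcol) + 2 * h;
            const double* g01 = g00 + Ho;
            gwk[0] += v * g00[0];
            gwk[1] += v * g00[1];
            gwk[2] += v * g01[0];
            gwk[3] += v * g01[1];
            gxc[h + (size_t)H * wcol] +=
              wk[0] * g00[0] + wk[1] * g00[1] + wk[2] * g01[0] + wk[3] * g01[1];
          }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  Returns the pooled map and the argmax code
// (0..3, column-major within the tile) needed for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx(out.size());
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = out.attr("dim");
  const double* xp = x.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = xp + (size_t)H * W * cn;
    double* oc = out.begin() + (size_t)Ho * Wo * cn;
    int* ic = idx.begin() + (size_t)Ho * Wo * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double* t = xc + (size_t)H * (2 * w) + 2 * h;
        double best = t[0];
        int bi = 0;
        if (t[1] > best) { best = t[1]; bi = 1; }
        if (t[H] > best) { best = t[H]; bi = 2; }
        if (t[H + 1] > best) { best = t[H + 1]; bi = 3; }
        oc[h + (size_t)Ho * w] = best;
        ic[h + (size_t)Ho * w] = bi;
      }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const IntegerVector& idx, const NumericVector& gout,
                               int H, int W) {
  IntegerVector od = gout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2];
  const int N = od.size() == 4 ? od[3] : 1;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gc = gout.begin() + (size_t)Ho * Wo * cn;
    const int* ic = idx.begin() + (size_t)Ho * Wo * cn;
    double* xc = gx.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int bi = ic[h + (size_t)Ho * w];
        xc[(size_t)H * (2 * w + bi / 2) + 2 * h + bi % 2] += gc[h + (size_t)Ho * w];
      }
  }
  return gx;
}

// For each row of A (m x 2, already spacing-scaled coordinates) the minimum
// Euclidean distance to any row of B.
// [[Rcpp::export]]
NumericVector min_dists_cpp(const NumericMatrix& A, const NumericMatrix& B) {
  const int m = A.nrow(), nb = B.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double ay = A(i, 0), ax = A(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dy = ay - B(j, 0), dx = ax - B(j, 1);
      const double d2 = dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
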