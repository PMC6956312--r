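// Minimal 3-D convolution engine (im2col + GEMM) used by the network builders.
//
// Tensor layout (column-major, R order): feature maps are arrays
// dim = c(D, H, W, C) — voxel index fastest, channel last, so channel
// concatenation is a plain c() at the R level.  Weights are arrays
// dim = c(kd, kh, kw, Cin, Cout): as a matrix (kd*kh*kw*Cin) x Cout.
//
// The im2col buffer is laid out voxels x (taps*channels) so that both the
// gather from the input and the write into the buffer run contiguously.
//
// A single routine family covers everything the package needs:
//  * stride-1 "valid"/"same"/"full" convolutions (pad argument),
//  * transpose convolutions (full padding of a flipped kernel, handled at
//    the R level),
//  * the critic's stride-2 SAME convolutions (ceil semantics, asymmetric
//    begin-padding as in common deep-learning frameworks).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvDims {
  int D, H, W, C;          // input
  int kd, kh, kw, Cin, Cout;
  int sd, sh, sw;          // stride
  int pd, ph, pw;          // begin padding
  int Do, Ho, Wo;          // output
  int ntap;
};

ConvDims make_dims(const IntegerVector& xdim, const IntegerVector& wdim,
                   const IntegerVector& stride, const IntegerVector& pad,
                   const IntegerVector& outdim) {
  ConvDims d;
  d.D = xdim[0]; d.H = xdim[1]; d.W = xdim[2]; d.C = xdim[3];
  d.kd = wdim[0]; d.kh = wdim[1]; d.kw = wdim[2]; d.Cin = wdim[3]; d.Cout = wdim[4];
  d.sd = stride[0]; d.sh = stride[1]; d.sw = stride[2];
  d.pd = pad[0]; d.ph = pad[1]; d.pw = pad[2];
  d.Do = outdim[0]; d.Ho = outdim[1]; d.Wo = outdim[2];
  d.ntap = d.kd * d.kh * d.kw;
  if (d.C != d.Cin) stop("conv3d: channel mismatch (input %d vs kernel %d)", d.C, d.Cin);
  return d;
}

// Fill one im2col column (fixed tap and input channel) for output voxels
// [v0, v0+nb): dst[b] = x[(od*sd-pd+zd, oh*sh-ph+zh, ow*sw-pw+zw, c)] or 0.
void fill_col(const double* xc, const ConvDims& d, int zd, int zh, int zw,
              int v0, int nb, double* dst) {
  int v = v0;
  int od = v % d.Do, rem = v / d.Do;
  int oh = rem % d.Ho, ow = rem / d.Ho;
  for (int b = 0; b < nb; ) {
    const int ih = oh * d.sh - d.ph + zh;
    const int iw = ow * d.sw - d.pw + zw;
    // run along od until the od-dimension wraps or the block ends
    int run = std::min(nb - b, d.Do - od);
    if (ih < 0 || ih >= d.H || iw < 0 || iw >= d.W) {
      std::fill(dst + b, dst + b + run, 0.0);
    } else {
      const double* src = xc + d.D * (ih + (R_xlen_t)d.H * iw);
      if (d.sd == 1) {
        const int id0 = od - d.pd + zd;
        const int lo = std::max(0, -id0);
        const int hi = std::min(run, d.D - id0);
        if (lo > 0) std::fill(dst + b, dst + b + std::min(lo, run), 0.0);
        if (hi > lo) std::memcpy(dst + b + lo, src + id0 + lo, (hi - lo) * sizeof(double));
        if (hi < run) std::fill(dst + b + std::max(hi, 0), dst + b + run, 0.0);
      } else {
        for (int t = 0; t < run; ++t) {
          const int id = (od + t) * d.sd - d.pd + zd;
          dst[b + t] = (id >= 0 && id < d.D) ? src[id] : 0.0;
        }
      }
    }
    b += run; od += run;
    if (od == d.Do) {
      od = 0;
      if (++oh == d.Ho) { oh = 0; ++ow; }
    }
  }
}

void im2col_block(const double* x, const ConvDims& d, int v0, int nb, arma::mat& K) {
  const R_xlen_t nvox_in = (R_xlen_t)d.D * d.H * d.W;
  // K is nb x (ntap*Cin); column index = tap + ntap*c
  for (int c = 0; c < d.Cin; ++c) {
    const double* xc = x + nvox_in * c;
    for (int zw = 0; zw < d.kw; ++zw)
      for (int zh = 0; zh < d.kh; ++zh)
        for (int zd = 0; zd < d.kd; ++zd) {
          const int tap = zd + d.kd * (zh + d.kh * zw);
          fill_col(xc, d, zd, zh, zw, v0, nb, K.colptr(tap + d.ntap * c));
        }
  }
}

const int BLOCK = 4096;

// Grow-only workspaces reused across calls (single-threaded R).
arma::mat work_mat(int id, int nr, int nc) {
  static std::vector<double> store[4];
  std::vector<double>& v = store[id];
  if (v.size() < (size_t)nr * nc) v.resize((size_t)nr * nc);
  return arma::mat(v.data(), nr, nc, false, true);
}

} // namespace

// [[Rcpp::export(name = ".nn_conv3d_fwd")]]
NumericVector nn_conv3d_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector bias,
                            IntegerVector stride, IntegerVector pad,
                            IntegerVector outdim) {
  ConvDims d = make_dims(xdim, wdim, stride, pad, outdim);
  const int nvox_out = d.Do * d.Ho * d.Wo;
  NumericVector y(static_cast<R_xlen_t>(nvox_out) * d.Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), d.ntap * d.Cin, d.Cout, false, true);
  for (int v0 = 0; v0 < nvox_out; v0 += BLOCK) {
    const int nb = std::min(BLOCK, nvox_out - v0);
    arma::mat K = work_mat(0, nb, d.ntap * d.Cin);
    im2col_block(x.begin(), d, v0, nb, K);
    arma::mat Yb = work_mat(1, nb, d.Cout);
    Yb = K * Wm;                          // nb x Cout
    for (int c = 0; c < d.Cout; ++c) {
      double* dst = y.begin() + static_cast<R_xlen_t>(c) * nvox_out + v0;
      const double* src = Yb.colptr(c);
      const double bc = bias[c];
      for (int b = 0; b < nb; ++b) dst[b] = src[b] + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(d.Do, d.Ho, d.Wo, d.Cout);
  return y;
}

// [[Rcpp::export(name = ".nn_conv3d_bwd_data")]]
NumericVector nn_conv3d_bwd_data(NumericVector gy, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 IntegerVector stride, IntegerVector pad,
                                 IntegerVector outdim) {
  ConvDims d = make_dims(xdim, wdim, stride, pad, outdim);
  const R_xlen_t nvox_in = (R_xlen_t)d.D * d.H * d.W;
  const int nvox_out = d.Do * d.Ho * d.Wo;
  NumericVector gx(nvox_in * d.C);
  arma::mat Wm(const_cast<double*>(w.begin()), d.ntap * d.Cin, d.Cout, false, true);
  for (int v0 = 0; v0 < nvox_out; v0 += BLOCK) {
    const int nb = std::min(BLOCK, nvox_out - v0);
    arma::mat Gb = work_mat(2, nb, d.Cout);
    for (int c = 0; c < d.Cout; ++c) {
      const double* src = gy.begin() + static_cast<R_xlen_t>(c) * nvox_out + v0;
      std::copy(src, src + nb, Gb.colptr(c));
    }
    arma::mat gK = work_mat(3, nb, d.ntap * d.Cin);
    gK = Gb * Wm.t();                     // nb x (ntap*Cin)
    // col2im scatter-add, one (tap, channel) column at a time
    for (int c = 0; c < d.Cin; ++c) {
      double* gxc = gx.begin() + nvox_in * c;
      for (int zw = 0; zw < d.kw; ++zw)
        for (int zh = 0; zh < d.kh; ++zh)
          for (int zd = 0; zd < d.kd; ++zd) {
            const int tap = zd + d.kd * (zh + d.kh * zw);
            const double* col = gK.colptr(tap + d.ntap * c);
            int v = v0;
            int od = v % d.Do, rem = v / d.Do;
            int oh = rem % d.Ho, ow = rem / d.Ho;
            for (int b = 0; b < nb; ) {
              const int ih = oh * d.sh - d.ph + zh;
              const int iw = ow * d.sw - d.pw + zw;
              int run = std::min(nb - b, d.Do - od);
              if (ih >= 0 && ih < d.H && iw >= 0 && iw < d.W) {
                double* dst = gxc + d.D * (ih + (R_xlen_t)d.H * iw);
                if (d.sd == 1) {
                  const int id0 = od - d.pd + zd;
                  const int lo = std::max(0, -id0);
                  const int hi = std::min(run, d.D - id0);
                  for (int t = lo; t < hi; ++t) dst[id0 + t] += col[b + t];
                } else {
                  for (int t = 0; t < run; ++t) {
                    const int id = (od + t) * d.sd - d.pd + zd;
                    if (id >= 0 && id < d.D) dst[id] += col[b + t];
                  }
                }
              }
              b += run; od += run;
              if (od == d.Do) {
                od = 0;
                if (++oh == d.Ho) { oh = 0; ++ow; }
              }
            }
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(d.D, d.H, d.W, d.C);
  return gx;
}

// [[Rcpp::export(name = ".nn_conv3d_bwd_wb")]]
List nn_conv3d_bwd_wb(NumericVector x, IntegerVector xdim,
                      NumericVector gy, IntegerVector wdim,
                      IntegerVector stride, IntegerVector pad,
                      IntegerVector outdim) {
  ConvDims d = make_dims(xdim, wdim, stride, pad, outdim);
  const int nvox_out = d.Do * d.Ho * d.Wo;
  arma::mat gW(d.ntap * d.Cin, d.Cout, arma::fill::zeros);
  arma::rowvec gb(d.Cout, arma::fill::zeros);
  for (int v0 = 0; v0 < nvox_out; v0 += BLOCK) {
    const int nb = std::min(BLOCK, nvox_out - v0);
    arma::mat K = work_mat(0, nb, d.ntap * d.Cin);
    im2col_block(x.begin(), d, v0, nb, K);
    arma::mat Gb = work_mat(2, nb, d.Cout);
    for (int c = 0; c < d.Cout; ++c) {
      const double* src = gy.begin() + static_cast<R_xlen_t>(c) * nvox_out + v0;
      std::copy(src, src + nb, Gb.colptr(c));
    }
    gW += K.t() * Gb;
    gb += arma::sum(Gb, 0);
  }
  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = IntegerVector::create(d.kd, d.kh, d.kw, d.Cin, d.Cout);
  return List::create(_["gw"] = gWr, _["gb"] = NumericVector(gb.begin(), gb.end()));
}
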