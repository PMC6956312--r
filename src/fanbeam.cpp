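// Slice-wise equiangular fan-beam projector and distance-weighted
// backprojector.  World coordinates in mm: x to the right (columns),
// y upward (rows count downward), isocenter at the image center.
// The source for view angle beta sits at SID * (cos beta, sin beta);
// the ray at fan angle gamma leaves the source with direction
// -(cos(beta + gamma), sin(beta + gamma)), so its signed distance from
// the isocenter is SID * sin(gamma).

#include <Rcpp.h>
using namespace Rcpp;

static inline double bilinear(const double* img, int N, double px_mm,
                              double x_mm, double y_mm) {
  // grid: col j -> x = (j - (N-1)/2) * px ; row i -> y = ((N-1)/2 - i) * px
  const double half = (N - 1) / 2.0;
  const double fj = x_mm / px_mm + half;
  const double fi = half - y_mm / px_mm;
  const int j0 = (int)std::floor(fj), i0 = (int)std::floor(fi);
  if (j0 < -1 || j0 > N - 1 || i0 < -1 || i0 > N - 1) return 0.0;
  const double tj = fj - j0, ti = fi - i0;
  double v = 0.0;
  for (int dj = 0; dj <= 1; ++dj) {
    const int j = j0 + dj;
    if (j < 0 || j >= N) continue;
    const double wj = dj ? tj : 1.0 - tj;
    for (int di = 0; di <= 1; ++di) {
      const int i = i0 + di;
      if (i < 0 || i >= N) continue;
      const double wi = di ? ti : 1.0 - ti;
      v += wi * wj * img[i + N * j];   // column-major R matrix (row i, col j)
    }
  }
  return v;
}

// [[Rcpp::export(name = ".fan_forward")]]
NumericMatrix fan_forward(NumericMatrix img, double px_mm, double sid,
                          NumericVector betas, NumericVector gammas,
                          double step_mm) {
  const int N = img.nrow();
  if (img.ncol() != N) stop("fan_forward: image must be square");
  const int nv = betas.size(), nd = gammas.size();
  NumericMatrix sino(nv, nd);
  const double rsup = 0.5 * N * px_mm * std::sqrt(2.0) + 2.0 * px_mm;
  const double* ip = &img[0];
  for (int v = 0; v < nv; ++v) {
    const double b = betas[v];
    const double sx = sid * std::cos(b), sy = sid * std::sin(b);
    for (int d = 0; d < nd; ++d) {
      const double a = b + gammas[d];
      const double dx = -std::cos(a), dy = -std::sin(a);
      // integrate where the ray crosses the image support disc
      const double t0 = std::max(0.0, sid - rsup);
      const double t1 = sid + rsup;
      double acc = 0.0;
      for (double t = t0; t <= t1; t += step_mm)
        acc += bilinear(ip, N, px_mm, sx + t * dx, sy + t * dy);
      sino(v, d) = acc * step_mm;
    }
  }
  return sino;
}

// [[Rcpp::export(name = ".fan_backproject")]]
NumericMatrix fan_backproject(NumericMatrix q, double px_mm, double sid,
                              NumericVector betas, NumericVector gammas,
                              int N, double dbeta) {
  const int nv = betas.size(), nd = gammas.size();
  if (q.nrow() != nv || q.ncol() != nd) stop("fan_backproject: sinogram shape mismatch");
  const double g0 = gammas[0];
  const double dg = nd > 1 ? gammas[1] - gammas[0] : 1.0;
  NumericMatrix img(N, N);
  const double half = (N - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    const double b = betas[v];
    const double cb = std::cos(b), sb = std::sin(b);
    const double sx = sid * cb, sy = sid * sb;
    const double* qv = &q(v, 0);          // stride nv between detector samples
    for (int j = 0; j < N; ++j) {
      const double x = (j - half) * px_mm;
      for (int i = 0; i < N; ++i) {
        const double y = (half - i) * px_mm;
        const double vx = x - sx, vy = y - sy;
        const double par = -(vx * cb + vy * sb);         // along central ray
        const double perp = vx * sb - vy * cb;           // +gamma direction
        const double L2 = vx * vx + vy * vy;
        const double gp = std::atan2(perp, par);
        const double fd = (gp - g0) / dg;
        const int d0 = (int)std::floor(fd);
        if (d0 < 0 || d0 >= nd - 1) continue;
        const double td = fd - d0;
        const double qq = qv[(R_xlen_t)d0 * nv] * (1.0 - td) +
                          qv[((R_xlen_t)d0 + 1) * nv] * td;
        img(i, j) += dbeta * qq / L2;
      }
    }
  }
  return img;
}
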