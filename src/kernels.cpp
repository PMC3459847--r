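#include <Rcpp.h>
using namespace Rcpp;

// Velocity of the truncated method-of-images source flow on the unwrapped
// cylinder strip. Each source j of area flux Q[j] (um^2/s) is replicated at
// y + k*P for k = -kmax..kmax (nImages = 2*kmax+1 total terms); each image is
// a 2D point source with velocity (Q/2pi) * (r - r_jk) / |r - r_jk|^2.
//
// selfIdx: if length N, selfIdx[i] is the 1-based index (into the source
// list) whose k = 0 (direct) term is skipped when evaluating point i; 0 means
// no exclusion. Used to advect a source by the total field minus its own
// singular monopole.
// [[Rcpp::export]]
NumericMatrix cpp_velocity(NumericMatrix pts, NumericMatrix src,
                           NumericVector Q, double P, int nImages,
                           double eps, IntegerVector selfIdx) {
  const int N = pts.nrow(), M = src.nrow();
  if (nImages < 1 || nImages % 2 == 0)
    stop("nImages must be an odd positive integer");
  const int kmax = (nImages - 1) / 2;
  const double eps2 = eps * eps;
  const bool haveSelf = (selfIdx.size() == N);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) {
    const double px = pts(i, 0), py = pts(i, 1);
    const int self = haveSelf ? selfIdx[i] : 0;
    double vx = 0.0, vy = 0.0;
    for (int j = 0; j < M; ++j) {
      const double dx = px - src(j, 0);
      const double dy0 = py - src(j, 1);
      const double c = Q[j] / (2.0 * M_PI);
      for (int k = -kmax; k <= kmax; ++k) {
        if (k == 0 && self == j + 1) continue;
        const double dy = dy0 - k * P;
        const double r2 = dx * dx + dy * dy;
        if (r2 < eps2)
          stop("velocity evaluated within epsilon of a source image");
        vx += c * dx / r2;
        vy += c * dy / r2;
      }
    }
    out(i, 0) = vx;
    out(i, 1) = vy;
  }
  return out;
}

// Even-odd (crossing number) point-in-polygon test; polygon is a closed ring
// given without repetition of the first vertex.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector x, NumericVector y,
                                    NumericMatrix poly) {
  const int n = x.size(), m = poly.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = false;
    const double px = x[i], py = y[i];
    for (int a = 0, b = m - 1; a < m; b = a++) {
      const double ax = poly(a, 0), ay = poly(a, 1);
      const double bx = poly(b, 0), by = poly(b, 1);
      if (((ay > py) != (by > py)) &&
          (px < (bx - ax) * (py - ay) / (by - ay) + ax))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}
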