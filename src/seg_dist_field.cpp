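#include <Rcpp.h>
using namespace Rcpp;

// Exact Euclidean distance from every pixel center of a regular grid to the
// nearest of a set of straight segments, computed only inside a band of
// half-width maxdist around each segment (pixels outside every band keep Inf).
// Grid pixel (i, j), 1-based in R, has center (x0 + (i-1)*h, y0 + (j-1)*h).
//
// segs: matrix with columns x1, y1, x2, y2 (one straight piece per row).
// [[Rcpp::export]]
NumericMatrix seg_dist_field(NumericMatrix segs, double x0, double y0,
                             double h, int nx, int ny, double maxdist) {
  NumericMatrix D(nx, ny);
  std::fill(D.begin(), D.end(), R_PosInf);
  const int ns = segs.nrow();
  for (int s = 0; s < ns; ++s) {
    const double ax = segs(s, 0), ay = segs(s, 1);
    const double bx = segs(s, 2), by = segs(s, 3);
    const double xmin = std::min(ax, bx) - maxdist;
    const double xmax = std::max(ax, bx) + maxdist;
    const double ymin = std::min(ay, by) - maxdist;
    const double ymax = std::max(ay, by) + maxdist;
    int i0 = (int)std::ceil((xmin - x0) / h);
    int i1 = (int)std::floor((xmax - x0) / h);
    int j0 = (int)std::ceil((ymin - y0) / h);
    int j1 = (int)std::floor((ymax - y0) / h);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    const double dx = bx - ax, dy = by - ay;
    const double L2 = dx * dx + dy * dy;
    for (int j = j0; j <= j1; ++j) {
      const double py = y0 + j * h;
      for (int i = i0; i <= i1; ++i) {
        const double px = x0 + i * h;
        double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        const double ex = px - (ax + t * dx);
        const double ey = py - (ay + t * dy);
        const double d = std::sqrt(ex * ex + ey * ey);
        if (d < D(i, j)) D(i, j) = d;
      }
    }
  }
  return D;
}

// Minimum distance from each query point to the nearest segment.
// Used for exact point-in-sausage tests and snapping distances.
// [[Rcpp::export]]
NumericVector min_dist_to_segments(NumericMatrix pts, NumericMatrix segs) {
  const int np = pts.nrow(), ns = segs.nrow();
  NumericVector out(np, R_PosInf);
  for (int s = 0; s < ns; ++s) {
    const double ax = segs(s, 0), ay = segs(s, 1);
    const double bx = segs(s, 2), by = segs(s, 3);
    const double dx = bx - ax, dy = by - ay;
    const double L2 = dx * dx + dy * dy;
    for (int p = 0; p < np; ++p) {
      double t = L2 > 0 ? ((pts(p, 0) - ax) * dx + (pts(p, 1) - ay) * dy) / L2 : 0.0;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      const double ex = pts(p, 0) - (ax + t * dx);
      const double ey = pts(p, 1) - (ay + t * dy);
      const double d = std::sqrt(ex * ex + ey * ey);
      if (d < out[p]) out[p] = d;
    }
  }
  return out;
}
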