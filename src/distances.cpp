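#include <Rcpp.h>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// squared distance from point p to segment (a, b)
static inline double pt_seg_d2(double px, double py,
                               double ax, double ay,
                               double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  if (L2 <= 0.0) return sq(px - ax) + sq(py - ay);
  double t = ((px - ax) * dx + (py - ay) * dy) / L2;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  return sq(px - ax - t * dx) + sq(py - ay - t * dy);
}

// For each point in (ax, ay): Euclidean distance to the nearest point in (bx, by).
// [[Rcpp::export]]
NumericVector cpp_nearest_cross_dist(NumericVector ax, NumericVector ay,
                                     NumericVector bx, NumericVector by) {
  int n = ax.size(), m = bx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double xi = ax[i], yi = ay[i];
    for (int j = 0; j < m; ++j) {
      double d2 = sq(xi - bx[j]) + sq(yi - by[j]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each point: minimum distance to a set of segments, plus the group id
// (e.g. polygon / cluster index) owning the nearest segment.
// Segments given as parallel vectors; gid is a 1-based integer group label.
// [[Rcpp::export]]
List cpp_point_segments_dist(NumericVector px, NumericVector py,
                             NumericVector x1, NumericVector y1,
                             NumericVector x2, NumericVector y2,
                             IntegerVector gid) {
  int n = px.size(), m = x1.size();
  NumericVector dist(n);
  IntegerVector group(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bg = NA_INTEGER;
    for (int j = 0; j < m; ++j) {
      double d2 = pt_seg_d2(px[i], py[i], x1[j], y1[j], x2[j], y2[j]);
      if (d2 < best) { best = d2; bg = gid[j]; }
    }
    dist[i] = std::sqrt(best);
    group[i] = bg;
  }
  return List::create(_["dist"] = dist, _["group"] = group);
}

// Even-odd (ray casting) point-in-ring test; ring need not be closed.
// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericVector px, NumericVector py,
                                 NumericVector rx, NumericVector ry) {
  int n = px.size(), m = rx.size();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    bool in = false;
    double x = px[i], y = py[i];
    for (int j = 0, k = m - 1; j < m; k = j++) {
      bool cross = ((ry[j] > y) != (ry[k] > y)) &&
        (x < (rx[k] - rx[j]) * (y - ry[j]) / (ry[k] - ry[j]) + rx[j]);
      if (cross) in = !in;
    }
    inside[i] = in;
  }
  return inside;
}

// Minimum distance between two segment sets (polygon boundaries).
// Includes endpoint-to-segment distances from both sides, which covers the
// crossing case only when segments touch; callers combine with an
// inside/overlap test where needed.
// [[Rcpp::export]]
double cpp_min_segset_dist(NumericVector ax1, NumericVector ay1,
                           NumericVector ax2, NumericVector ay2,
                           NumericVector bx1, NumericVector by1,
                           NumericVector bx2, NumericVector by2) {
  int na = ax1.size(), nb = bx1.size();
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double d2 = pt_seg_d2(ax1[i], ay1[i], bx1[j], by1[j], bx2[j], by2[j]);
      double t  = pt_seg_d2(ax2[i], ay2[i], bx1[j], by1[j], bx2[j], by2[j]);
      if (t < d2) d2 = t;
      t = pt_seg_d2(bx1[j], by1[j], ax1[i], ay1[i], ax2[i], ay2[i]);
      if (t < d2) d2 = t;
      t = pt_seg_d2(bx2[j], by2[j], ax1[i], ay1[i], ax2[i], ay2[i]);
      if (t < d2) d2 = t;
      if (d2 < best) best = d2;
      if (best == 0.0) return 0.0;
    }
  }
  return std::sqrt(best);
}
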