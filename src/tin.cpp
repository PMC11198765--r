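#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

// Bowyer-Watson incremental Delaunay triangulation. Inputs are expected to
// be deduplicated and (for gridded data) lightly jittered by the caller to
// break cocircular degeneracies. Indices in the result are 1-based rows of
// the input.

struct Tri {
  int a, b, c;
  bool alive;
};

static inline bool incircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double px, double py) {
  // assumes abc counter-clockwise; > 0 when p lies inside the circumcircle
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
               ad * (bdx * cdy - bdy * cdx);
  return det > 0.0;
}

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points to triangulate");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0.0) stop("degenerate point set (all points coincide)");
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  px[n] = cx - 30.0 * dmax; py[n] = cy - 20.0 * dmax;
  px[n + 1] = cx + 30.0 * dmax; py[n + 1] = cy - 20.0 * dmax;
  px[n + 2] = cx; py[n + 2] = cy + 30.0 * dmax;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  std::map<Edge, int> edge_count;
  for (int ip = 0; ip < n; ++ip) {
    bad.clear();
    edge_count.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& T = tris[t];
      if (incircle(px[T.a], py[T.a], px[T.b], py[T.b], px[T.c], py[T.c],
                   px[ip], py[ip]))
        bad.push_back(t);
    }
    for (int t : bad) {
      const Tri& T = tris[t];
      int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (auto& ed : e) {
        Edge key(std::min(ed[0], ed[1]), std::max(ed[0], ed[1]));
        edge_count[key]++;
      }
      tris[t].alive = false;
    }
    // boundary edges of the cavity appear exactly once
    for (auto& kv : edge_count) {
      if (kv.second != 1) continue;
      int a = kv.first.first, b = kv.first.second;
      if (orient2d(px[a], py[a], px[b], py[b], px[ip], py[ip]) < 0.0)
        std::swap(a, b);
      tris.push_back({a, b, ip, true});
    }
  }
  int count = 0;
  for (const Tri& T : tris)
    if (T.alive && T.a < n && T.b < n && T.c < n) ++count;
  IntegerMatrix out(count, 3);
  int k = 0;
  for (const Tri& T : tris) {
    if (!(T.alive && T.a < n && T.b < n && T.c < n)) continue;
    out(k, 0) = T.a + 1; out(k, 1) = T.b + 1; out(k, 2) = T.c + 1;
    ++k;
  }
  return out;
}

// Rasterize a TIN by barycentric linear interpolation at cell centers.
// tri is 1-based. Grid cell (i, j) center: (origin_x + (j + 0.5) * cell,
// origin_y + (i + 0.5) * cell); returned matrix is ny rows x nx cols with
// NA outside the triangulation.
// [[Rcpp::export]]
NumericMatrix tin_rasterize_cpp(NumericVector x, NumericVector y,
                                NumericVector z, IntegerMatrix tri,
                                double origin_x, double origin_y, double cell,
                                int nx, int ny) {
  NumericMatrix grid(ny, nx);
  std::fill(grid.begin(), grid.end(), NA_REAL);
  const double eps = 1e-9;
  for (int t = 0; t < tri.nrow(); ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    double ax = x[a], ay = y[a], bx = x[b], by = y[b], cx = x[c], cy = y[c];
    double det = (by - ay) * (cx - ax) - (bx - ax) * (cy - ay);
    if (std::fabs(det) < 1e-14) continue;
    double txmin = std::min(ax, std::min(bx, cx));
    double txmax = std::max(ax, std::max(bx, cx));
    double tymin = std::min(ay, std::min(by, cy));
    double tymax = std::max(ay, std::max(by, cy));
    int j0 = std::max(0, (int)std::floor((txmin - origin_x) / cell - 0.5));
    int j1 = std::min(nx - 1, (int)std::ceil((txmax - origin_x) / cell - 0.5));
    int i0 = std::max(0, (int)std::floor((tymin - origin_y) / cell - 0.5));
    int i1 = std::min(ny - 1, (int)std::ceil((tymax - origin_y) / cell - 0.5));
    for (int i = i0; i <= i1; ++i) {
      double pyc = origin_y + (i + 0.5) * cell;
      for (int j = j0; j <= j1; ++j) {
        double pxc = origin_x + (j + 0.5) * cell;
        double l1 = ((by - cy) * (pxc - cx) + (cx - bx) * (pyc - cy)) /
                    ((by - cy) * (ax - cx) + (cx - bx) * (ay - cy));
        double l2 = ((cy - ay) * (pxc - cx) + (ax - cx) * (pyc - cy)) /
                    ((by - cy) * (ax - cx) + (cx - bx) * (ay - cy));
        double l3 = 1.0 - l1 - l2;
        if (l1 < -eps || l2 < -eps || l3 < -eps) continue;
        grid(i, j) = l1 * z[a] + l2 * z[b] + l3 * z[c];
      }
    }
  }
  return grid;
}
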