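#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Terrain evaluation. type 0: plane z0 + sx*x + sy*y (tparams = z0, sx, sy).
// type 1: Gaussian hills, tparams = z0, hills rows = (x, y, amp, sigma).
static inline double terrain_f(double x, double y, int type,
                               const NumericVector& tp,
                               const NumericMatrix& hills) {
  if (type == 0) return tp[0] + tp[1] * x + tp[2] * y;
  double z = tp[0];
  for (int i = 0; i < hills.nrow(); ++i) {
    double dx = x - hills(i, 0), dy = y - hills(i, 1);
    double s2 = hills(i, 3) * hills(i, 3);
    z += hills(i, 2) * std::exp(-(dx * dx + dy * dy) / (2.0 * s2));
  }
  return z;
}

struct Ray {
  double ox, oy, oz, dx, dy, dz;
};

// height of the ray above the terrain at parameter t
static inline double above(const Ray& r, double t, int type,
                           const NumericVector& tp, const NumericMatrix& hills) {
  return r.oz + t * r.dz -
         terrain_f(r.ox + t * r.dx, r.oy + t * r.dy, type, tp, hills);
}

// first terrain intersection by bounded marching + bisection (<= 0.1 mm)
static double terrain_hit(const Ray& r, int type, const NumericVector& tp,
                          const NumericMatrix& hills, double max_range,
                          double band_lo, double band_hi, double step,
                          bool force_march) {
  if (type == 0 && !force_march) {
    // closed form: above(t) is linear in t for planar terrain
    double g0 = above(r, 0.0, type, tp, hills);
    double g1 = above(r, 1.0, type, tp, hills);
    double slope = g1 - g0;
    if (g0 <= 0.0) return 0.0;
    if (slope >= 0.0) return -1.0;
    double t = -g0 / slope;
    return (t <= max_range) ? t : -1.0;
  }
  // restrict the march to the t-interval where the ray is inside the
  // terrain elevation band
  double lo = 0.0, hi = max_range;
  if (std::fabs(r.dz) > 1e-12) {
    double t_a = (band_lo - r.oz) / r.dz, t_b = (band_hi - r.oz) / r.dz;
    if (t_a > t_b) std::swap(t_a, t_b);
    lo = std::max(lo, t_a);
    hi = std::min(hi, t_b);
  } else if (r.oz < band_lo || r.oz > band_hi) {
    return -1.0;
  }
  if (lo > hi) return -1.0;
  double t_prev = lo;
  double g_prev = above(r, t_prev, type, tp, hills);
  if (g_prev <= 0.0 && lo == 0.0) return 0.0;  // origin on/under terrain
  while (t_prev < hi) {
    double t_next = std::min(t_prev + step, hi);
    double g_next = above(r, t_next, type, tp, hills);
    if (g_prev > 0.0 && g_next <= 0.0) {
      double a = t_prev, b = t_next;
      for (int k = 0; k < 40 && (b - a) > 1e-4; ++k) {
        double m = 0.5 * (a + b);
        if (above(r, m, type, tp, hills) > 0.0) a = m; else b = m;
      }
      return 0.5 * (a + b);
    }
    t_prev = t_next;
    g_prev = g_next;
    if (t_next >= hi) break;
  }
  return -1.0;
}

// first hit on a finite vertical cylinder (no caps)
static double cylinder_hit(const Ray& r, double cx, double cy, double z_lo,
                           double z_hi, double radius, double max_range) {
  double ox = r.ox - cx, oy = r.oy - cy;
  double a = r.dx * r.dx + r.dy * r.dy;
  if (a < 1e-14) return -1.0;
  double b = 2.0 * (ox * r.dx + oy * r.dy);
  double c = ox * ox + oy * oy - radius * radius;
  double disc = b * b - 4.0 * a * c;
  if (disc < 0.0) return -1.0;
  double sq = std::sqrt(disc);
  for (double t : {(-b - sq) / (2.0 * a), (-b + sq) / (2.0 * a)}) {
    if (t < 0.0 || t > max_range) continue;
    double z = r.oz + t * r.dz;
    if (z >= z_lo && z <= z_hi) return t;
  }
  return -1.0;
}

// entry/exit parameters of the chord through an ellipsoid of revolution;
// returns false when the ray misses
static bool ellipsoid_chord(const Ray& r, double cx, double cy, double cz,
                            double a_h, double c_v, double& t1, double& t2) {
  double ox = (r.ox - cx) / a_h, oy = (r.oy - cy) / a_h, oz = (r.oz - cz) / c_v;
  double dx = r.dx / a_h, dy = r.dy / a_h, dz = r.dz / c_v;
  double A = dx * dx + dy * dy + dz * dz;
  double B = 2.0 * (ox * dx + oy * dy + oz * dz);
  double C = ox * ox + oy * oy + oz * oz - 1.0;
  double disc = B * B - 4.0 * A * C;
  if (disc < 0.0) return false;
  double sq = std::sqrt(disc);
  t1 = (-B - sq) / (2.0 * A);
  t2 = (-B + sq) / (2.0 * A);
  return t2 >= 0.0;
}

// counter-based uniform in (0, 1): splitmix64 of (seed, ray, tree), so the
// foliage draw for a given pulse/tree pair is independent of evaluation
// order and reproducible across runs
static inline double hash_uniform(uint64_t seed, uint64_t ray, uint64_t tree) {
  uint64_t x = seed * 0x9E3779B97F4A7C15ULL + ray * 0xBF58476D1CE4E5B9ULL +
               tree * 0x94D049BB133111EBULL + 0x2545F4914F6CDD1DULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return (static_cast<double>(x >> 11) + 0.5) / 9007199254740992.0;
}

// chord through a downward-opening cone (apex at (cx, cy, z_top), base
// radius R at z_base), bounded by the lateral surface and the base disk
static bool cone_chord(const Ray& r, double cx, double cy, double z_base,
                       double z_top, double R, double& t1, double& t2) {
  double k = R / (z_top - z_base);
  double ox = r.ox - cx, oy = r.oy - cy, oz = r.oz - z_top;
  double A = r.dx * r.dx + r.dy * r.dy - k * k * r.dz * r.dz;
  double B = 2.0 * (ox * r.dx + oy * r.dy - k * k * oz * r.dz);
  double C = ox * ox + oy * oy - k * k * oz * oz;
  double ts[3];
  int n = 0;
  if (std::fabs(A) < 1e-14) {
    if (std::fabs(B) > 1e-14) {
      double t = -C / B;
      double z = r.oz + t * r.dz;
      if (z >= z_base && z <= z_top) ts[n++] = t;
    }
  } else {
    double disc = B * B - 4.0 * A * C;
    if (disc >= 0.0) {
      double sq = std::sqrt(disc);
      for (double t : {(-B - sq) / (2.0 * A), (-B + sq) / (2.0 * A)}) {
        double z = r.oz + t * r.dz;
        if (z >= z_base && z <= z_top) ts[n++] = t;
      }
    }
  }
  if (std::fabs(r.dz) > 1e-14) {
    double t = (z_base - r.oz) / r.dz;
    double px = r.ox + t * r.dx - cx, py = r.oy + t * r.dy - cy;
    if (px * px + py * py <= R * R) ts[n++] = t;
  }
  if (n == 0) return false;
  t1 = t2 = ts[0];
  for (int i = 1; i < n; ++i) {
    t1 = std::min(t1, ts[i]);
    t2 = std::max(t2, ts[i]);
  }
  return t2 >= 0.0;
}

// Cast many rays against the scene. trees columns: x, y, base_z,
// trunk_radius, trunk_height, total_height, crown_type (0 ellipsoid,
// 1 cone), crown_radius, crown_extinction (per meter; >= 1e5 treated as an
// opaque surface). Porous crowns attenuate the ray along its chord with a
// Beer-Lambert law; the return point is drawn from the corresponding
// exponential depth using a counter-based hash RNG keyed on (seed, pulse,
// tree). Returns per-ray distance (-1 = miss) and hit type (-1 miss,
// 0 terrain, 1 trunk, 2 crown).
// [[Rcpp::export]]
List raycast_cpp(NumericMatrix origin, NumericMatrix dir, int terrain_type,
                 NumericVector tparams, NumericMatrix hills,
                 NumericMatrix trees, double max_range, double band_lo,
                 double band_hi, double march_step, bool force_march,
                 double seed) {
  const int n = origin.nrow();
  NumericVector dist(n);
  IntegerVector hit(n);
  const int ntree = trees.nrow();
  for (int i = 0; i < n; ++i) {
    Ray r{origin(i, 0), origin(i, 1), origin(i, 2),
          dir(i, 0), dir(i, 1), dir(i, 2)};
    double best = terrain_hit(r, terrain_type, tparams, hills, max_range,
                              band_lo, band_hi, march_step, force_march);
    int what = best >= 0.0 ? 0 : -1;
    for (int j = 0; j < ntree; ++j) {
      double cx = trees(j, 0), cy = trees(j, 1), bz = trees(j, 2);
      double tr = trees(j, 3), th = trees(j, 4), tot = trees(j, 5);
      double cr = trees(j, 7);
      double rmax = std::max(tr, cr);
      // quick reject: closest approach of the horizontal ray line
      double px = cx - r.ox, py = cy - r.oy;
      double hd2 = r.dx * r.dx + r.dy * r.dy;
      if (hd2 > 1e-14) {
        double tproj = (px * r.dx + py * r.dy) / hd2;
        if (tproj < -rmax) continue;
        double qx = px - tproj * r.dx, qy = py - tproj * r.dy;
        if (qx * qx + qy * qy > (rmax + 0.01) * (rmax + 0.01)) continue;
      } else if (px * px + py * py > rmax * rmax) {
        continue;
      }
      double cap = (best >= 0.0) ? best : max_range;
      double t = cylinder_hit(r, cx, cy, bz, bz + th, tr, cap);
      if (t >= 0.0 && (best < 0.0 || t < best)) { best = t; what = 1; }
      cap = (best >= 0.0) ? best : max_range;
      double t1, t2;
      bool chord;
      if ((int)trees(j, 6) == 0) {
        double c_v = 0.5 * (tot - th);
        chord = ellipsoid_chord(r, cx, cy, bz + th + c_v, cr, c_v, t1, t2);
      } else {
        chord = cone_chord(r, cx, cy, bz + th, bz + tot, cr, t1, t2);
      }
      if (chord) {
        double start = std::max(t1, 0.0);
        double k_ext = trees(j, 8);
        double tc = -1.0;
        if (k_ext >= 1e5) {
          tc = start;  // opaque crown: hit at the surface
        } else if (k_ext > 0.0) {
          double u = hash_uniform((uint64_t)seed, (uint64_t)i, (uint64_t)j);
          double depth = -std::log(u) / k_ext;
          if (start + depth <= t2) tc = start + depth;
        }
        if (tc >= 0.0 && tc <= cap && (best < 0.0 || tc < best)) {
          best = tc; what = 2;
        }
      }
    }
    dist[i] = best >= 0.0 ? best : NA_REAL;
    hit[i] = what;
  }
  return List::create(_["distance"] = dist, _["hit"] = hit);
}
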