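// Ray-mesh and voxel-mesh geometry kernels.
// Meshes arrive as an n x 3 vertex matrix and an m x 3 1-based face
// index matrix. Ray queries run through a uniform-grid accelerator
// traversed by 3D-DDA; each triangle carries a per-ray stamp so it is
// tested at most once per ray, which makes the result identical to the
// brute-force Moller-Trumbore loop.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// Moller-Trumbore on precomputed (v0, e1, e2); true for t > 1e-12.
inline bool ray_tri_pre(const double *T, const Vec3 &orig, const Vec3 &dir,
                        double &t) {
  const double eps = 1e-12;
  Vec3 v0 = v3(T[0], T[1], T[2]);
  Vec3 e1 = v3(T[3], T[4], T[5]);
  Vec3 e2 = v3(T[6], T[7], T[8]);
  Vec3 p = cross(dir, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  Vec3 s = sub(orig, v0);
  double u = dot(s, p) * inv;
  if (u < -eps || u > 1.0 + eps) return false;
  Vec3 q = cross(s, e1);
  double v = dot(dir, q) * inv;
  if (v < -eps || u + v > 1.0 + eps) return false;
  t = dot(e2, q) * inv;
  return t > 1e-12;
}

struct Accel {
  std::vector<double> tri; // nf * 9: v0, e1 = v1-v0, e2 = v2-v0
  int nf;
  double bmin[3], bmax[3];
  int gd[3];
  double cell[3];
  std::vector<std::vector<int>> cells;
  std::vector<int> stamp;
  int ray_id;

  void build(const NumericMatrix &V, const IntegerMatrix &F) {
    nf = F.nrow();
    tri.resize((size_t)nf * 9);
    for (int d = 0; d < 3; ++d) { bmin[d] = R_PosInf; bmax[d] = R_NegInf; }
    for (int i = 0; i < V.nrow(); ++i)
      for (int d = 0; d < 3; ++d) {
        bmin[d] = std::min(bmin[d], V(i, d));
        bmax[d] = std::max(bmax[d], V(i, d));
      }
    for (int d = 0; d < 3; ++d) {
      double pad = 1e-9 + 1e-9 * (bmax[d] - bmin[d]);
      bmin[d] -= pad; bmax[d] += pad;
    }
    int g = (int)std::ceil(std::cbrt((double)std::max(nf, 1)));
    g = std::max(1, std::min(g, 64));
    for (int d = 0; d < 3; ++d) {
      gd[d] = g;
      cell[d] = (bmax[d] - bmin[d]) / g;
      if (cell[d] <= 0) { gd[d] = 1; cell[d] = 1.0; }
    }
    cells.assign((size_t)gd[0] * gd[1] * gd[2], {});
    for (int f = 0; f < nf; ++f) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      double v0[3] = {V(a, 0), V(a, 1), V(a, 2)};
      double v1[3] = {V(b, 0), V(b, 1), V(b, 2)};
      double v2[3] = {V(c, 0), V(c, 1), V(c, 2)};
      double *T = &tri[(size_t)f * 9];
      for (int d = 0; d < 3; ++d) {
        T[d] = v0[d]; T[3 + d] = v1[d] - v0[d]; T[6 + d] = v2[d] - v0[d];
      }
      int lo[3], hi[3];
      for (int d = 0; d < 3; ++d) {
        double mn = std::min(v0[d], std::min(v1[d], v2[d]));
        double mx = std::max(v0[d], std::max(v1[d], v2[d]));
        lo[d] = std::max(0, std::min(gd[d] - 1, (int)((mn - bmin[d]) / cell[d])));
        hi[d] = std::max(0, std::min(gd[d] - 1, (int)((mx - bmin[d]) / cell[d])));
      }
      for (int k = lo[2]; k <= hi[2]; ++k)
        for (int j = lo[1]; j <= hi[1]; ++j)
          for (int i = lo[0]; i <= hi[0]; ++i)
            cells[i + gd[0] * (j + (size_t)gd[1] * k)].push_back(f);
    }
    stamp.assign(nf, -1);
    ray_id = 0;
  }

  // Collect ray parameters of every crossing with t > 0 (whole half-line).
  void ray_hits(const Vec3 &orig, const Vec3 &dir, std::vector<double> &ts) {
    ++ray_id;
    // slab clip against the grid bounding box
    double t0 = 0.0, t1 = R_PosInf;
    const double *o = &orig.x, *dd = &dir.x;
    for (int d = 0; d < 3; ++d) {
      double od = (&orig.x)[d], ddd = (&dir.x)[d];
      if (std::fabs(ddd) < 1e-300) {
        if (od < bmin[d] || od > bmax[d]) return;
      } else {
        double ta = (bmin[d] - od) / ddd, tb = (bmax[d] - od) / ddd;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    (void)o; (void)dd;
    if (t1 < t0) return;
    double tcur = t0 + 1e-12;
    // entry cell
    int ic[3], step[3];
    double tmaxv[3], tdelta[3];
    for (int d = 0; d < 3; ++d) {
      double pd = (&orig.x)[d] + tcur * (&dir.x)[d];
      ic[d] = std::max(0, std::min(gd[d] - 1, (int)((pd - bmin[d]) / cell[d])));
      double ddd = (&dir.x)[d];
      if (ddd > 1e-300) {
        step[d] = 1;
        tmaxv[d] = ((bmin[d] + (ic[d] + 1) * cell[d]) - (&orig.x)[d]) / ddd;
        tdelta[d] = cell[d] / ddd;
      } else if (ddd < -1e-300) {
        step[d] = -1;
        tmaxv[d] = ((bmin[d] + ic[d] * cell[d]) - (&orig.x)[d]) / ddd;
        tdelta[d] = -cell[d] / ddd;
      } else {
        step[d] = 0;
        tmaxv[d] = R_PosInf;
        tdelta[d] = R_PosInf;
      }
    }
    double t;
    for (;;) {
      const std::vector<int> &lst = cells[ic[0] + gd[0] * (ic[1] + (size_t)gd[1] * ic[2])];
      for (int f : lst) {
        if (stamp[f] == ray_id) continue;
        stamp[f] = ray_id;
        if (ray_tri_pre(&tri[(size_t)f * 9], orig, dir, t)) ts.push_back(t);
      }
      int d = 0;
      if (tmaxv[1] < tmaxv[d]) d = 1;
      if (tmaxv[2] < tmaxv[d]) d = 2;
      if (tmaxv[d] > t1 + 1e-12) break;
      ic[d] += step[d];
      if (ic[d] < 0 || ic[d] >= gd[d]) break;
      tmaxv[d] += tdelta[d];
    }
  }

  int ray_crossings(const Vec3 &orig, const Vec3 &dir, std::vector<double> &buf) {
    buf.clear();
    ray_hits(orig, dir, buf);
    return (int)buf.size();
  }
};

// xorshift/splitmix PRNG for per-point deterministic ray directions.
inline uint64_t splitmix(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
inline double u01(uint64_t &s) {
  return (splitmix(s) >> 11) * (1.0 / 9007199254740992.0);
}

inline Vec3 random_dir(uint64_t &s) {
  for (;;) {
    double x = 2.0 * u01(s) - 1.0, y = 2.0 * u01(s) - 1.0, z = 2.0 * u01(s) - 1.0;
    double n2 = x * x + y * y + z * z;
    if (n2 > 1e-4 && n2 < 1.0) {
      double n = std::sqrt(n2);
      return v3(x / n, y / n, z / n);
    }
  }
}

} // namespace

// Parity-based inside/outside labels: per point, majority vote over
// `nrays` pseudo-random ray directions seeded by (seed, point index).
// [[Rcpp::export]]
IntegerVector cpp_ray_parity_labels(NumericMatrix V, IntegerMatrix F,
                                    NumericMatrix P, int nrays, double seed) {
  Accel ac;
  ac.build(V, F);
  int np = P.nrow();
  IntegerVector out(np);
  uint64_t base = (uint64_t)(int64_t)seed;
  std::vector<double> buf;
  for (int i = 0; i < np; ++i) {
    Vec3 orig = v3(P(i, 0), P(i, 1), P(i, 2));
    int votes = 0;
    for (int r = 0; r < nrays; ++r) {
      uint64_t s = base * 1000003ULL + (uint64_t)i * 31ULL + (uint64_t)r;
      Vec3 dir = random_dir(s);
      if (ac.ray_crossings(orig, dir, buf) % 2 == 1) ++votes;
    }
    out[i] = (2 * votes > nrays) ? 1 : 0;
  }
  return out;
}

// Crossing counts for caller-supplied ray directions (one per point);
// used by the ray-direction-invariance property test.
// [[Rcpp::export]]
IntegerVector cpp_ray_crossings(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix O, NumericMatrix D) {
  Accel ac;
  ac.build(V, F);
  int n = O.nrow();
  IntegerVector out(n);
  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    out[i] = ac.ray_crossings(v3(O(i, 0), O(i, 1), O(i, 2)),
                              v3(D(i, 0), D(i, 1), D(i, 2)), buf);
  }
  return out;
}

// Total interior chord length per ray: sort crossing parameters and sum
// the inside intervals. An unpaired trailing crossing (grazing) is dropped.
// [[Rcpp::export]]
NumericVector cpp_ray_chords(NumericMatrix V, IntegerMatrix F,
                             NumericMatrix O, NumericMatrix D) {
  Accel ac;
  ac.build(V, F);
  int n = O.nrow();
  NumericVector out(n);
  std::vector<double> ts;
  for (int i = 0; i < n; ++i) {
    ts.clear();
    ac.ray_hits(v3(O(i, 0), O(i, 1), O(i, 2)),
                v3(D(i, 0), D(i, 1), D(i, 2)), ts);
    std::sort(ts.begin(), ts.end());
    double len = 0.0;
    for (size_t k = 0; k + 1 < ts.size(); k += 2) len += ts[k + 1] - ts[k];
    out[i] = len;
  }
  return out;
}

// Classify all grid points of an nx x ny x nz lattice by one parity
// sweep per (x, y) column: a single near-axial +z ray yields the inside
// intervals for the whole column. Point (i,j,k) sits at
// origin + (i,j,k) * pitch.
// [[Rcpp::export]]
IntegerVector cpp_grid_parity(NumericMatrix V, IntegerMatrix F,
                              IntegerVector dims, NumericVector origin,
                              double pitch) {
  Accel ac;
  ac.build(V, F);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(nx * (R_xlen_t)ny * nz);
  std::vector<double> ts;
  Vec3 dir = v3(3.1e-8, -2.3e-8, 1.0); // near-axial, avoids lattice grazing
  double nrm = std::sqrt(dot(dir, dir));
  dir = v3(dir.x / nrm, dir.y / nrm, dir.z / nrm);
  double z0 = origin[2] - 1.0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      Vec3 orig = v3(origin[0] + i * pitch + 1.7e-9,
                     origin[1] + j * pitch + 0.9e-9, z0);
      ts.clear();
      ac.ray_hits(orig, dir, ts);
      std::sort(ts.begin(), ts.end());
      for (int k = 0; k < nz; ++k) {
        double zt = (origin[2] + k * pitch) - z0; // ray param ~ z distance
        size_t below = std::upper_bound(ts.begin(), ts.end(), zt) - ts.begin();
        out[i + nx * (j + (R_xlen_t)ny * k)] = (below % 2 == 1) ? 1 : 0;
      }
    }
  }
  return out;
}

namespace {
// Akenine-Moller triangle-box overlap (separating axis test).
inline bool axis_test(double p0, double p1, double rad) {
  double mn = std::min(p0, p1), mx = std::max(p0, p1);
  return !(mn > rad || mx < -rad);
}

bool tri_box_overlap(const Vec3 &c, const Vec3 &h, Vec3 t0, Vec3 t1, Vec3 t2) {
  t0 = sub(t0, c); t1 = sub(t1, c); t2 = sub(t2, c);
  Vec3 e0 = sub(t1, t0), e1 = sub(t2, t1), e2 = sub(t0, t2);

  double fex = std::fabs(e0.x), fey = std::fabs(e0.y), fez = std::fabs(e0.z);
  if (!axis_test(e0.z * t0.y - e0.y * t0.z, e0.z * t2.y - e0.y * t2.z,
                 fez * h.y + fey * h.z)) return false;
  if (!axis_test(-e0.z * t0.x + e0.x * t0.z, -e0.z * t2.x + e0.x * t2.z,
                 fez * h.x + fex * h.z)) return false;
  if (!axis_test(e0.y * t1.x - e0.x * t1.y, e0.y * t2.x - e0.x * t2.y,
                 fey * h.x + fex * h.y)) return false;

  fex = std::fabs(e1.x); fey = std::fabs(e1.y); fez = std::fabs(e1.z);
  if (!axis_test(e1.z * t0.y - e1.y * t0.z, e1.z * t2.y - e1.y * t2.z,
                 fez * h.y + fey * h.z)) return false;
  if (!axis_test(-e1.z * t0.x + e1.x * t0.z, -e1.z * t2.x + e1.x * t2.z,
                 fez * h.x + fex * h.z)) return false;
  if (!axis_test(e1.y * t0.x - e1.x * t0.y, e1.y * t1.x - e1.x * t1.y,
                 fey * h.x + fex * h.y)) return false;

  fex = std::fabs(e2.x); fey = std::fabs(e2.y); fez = std::fabs(e2.z);
  if (!axis_test(e2.z * t0.y - e2.y * t0.z, e2.z * t1.y - e2.y * t1.z,
                 fez * h.y + fey * h.z)) return false;
  if (!axis_test(-e2.z * t0.x + e2.x * t0.z, -e2.z * t1.x + e2.x * t1.z,
                 fez * h.x + fex * h.z)) return false;
  if (!axis_test(e2.y * t1.x - e2.x * t1.y, e2.y * t2.x - e2.x * t2.y,
                 fey * h.x + fex * h.y)) return false;

  auto minmax3 = [](double a, double b, double cc, double &mn, double &mx) {
    mn = std::min(a, std::min(b, cc)); mx = std::max(a, std::max(b, cc));
  };
  double mn, mx;
  minmax3(t0.x, t1.x, t2.x, mn, mx); if (mn > h.x || mx < -h.x) return false;
  minmax3(t0.y, t1.y, t2.y, mn, mx); if (mn > h.y || mx < -h.y) return false;
  minmax3(t0.z, t1.z, t2.z, mn, mx); if (mn > h.z || mx < -h.z) return false;

  Vec3 n = cross(e0, e1);
  double d = -dot(n, t0);
  double r = h.x * std::fabs(n.x) + h.y * std::fabs(n.y) + h.z * std::fabs(n.z);
  if (d > r || d < -r) return false;
  return true;
}
} // namespace

// Mark voxels (voxel (i,j,k) spans origin + [i, i+1] x ... * pitch)
// whose cube overlaps any triangle.
// [[Rcpp::export]]
LogicalVector cpp_surface_voxels(NumericMatrix V, IntegerMatrix F,
                                 IntegerVector dims, NumericVector origin,
                                 double pitch) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(nx * (R_xlen_t)ny * nz, false);
  Vec3 h = v3(pitch / 2, pitch / 2, pitch / 2);
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    Vec3 t0 = v3(V(a, 0), V(a, 1), V(a, 2));
    Vec3 t1 = v3(V(b, 0), V(b, 1), V(b, 2));
    Vec3 t2 = v3(V(c, 0), V(c, 1), V(c, 2));
    double mnx = std::min(t0.x, std::min(t1.x, t2.x));
    double mxx = std::max(t0.x, std::max(t1.x, t2.x));
    double mny = std::min(t0.y, std::min(t1.y, t2.y));
    double mxy = std::max(t0.y, std::max(t1.y, t2.y));
    double mnz = std::min(t0.z, std::min(t1.z, t2.z));
    double mxz = std::max(t0.z, std::max(t1.z, t2.z));
    int i0 = std::max(0, (int)std::floor((mnx - origin[0]) / pitch));
    int i1 = std::min(nx - 1, (int)std::floor((mxx - origin[0]) / pitch));
    int j0 = std::max(0, (int)std::floor((mny - origin[1]) / pitch));
    int j1 = std::min(ny - 1, (int)std::floor((mxy - origin[1]) / pitch));
    int k0 = std::max(0, (int)std::floor((mnz - origin[2]) / pitch));
    int k1 = std::min(nz - 1, (int)std::floor((mxz - origin[2]) / pitch));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          R_xlen_t idx = i + nx * (j + (R_xlen_t)ny * k);
          if (out[idx]) continue;
          Vec3 cc = v3(origin[0] + (i + 0.5) * pitch,
                       origin[1] + (j + 0.5) * pitch,
                       origin[2] + (k + 0.5) * pitch);
          if (tri_box_overlap(cc, h, t0, t1, t2)) out[idx] = true;
        }
  }
  return out;
}
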