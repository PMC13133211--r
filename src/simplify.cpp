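// Quadric error metric edge-collapse simplification for closed triangle
// meshes. Pass-based greedy scheme with a growing error threshold;
// collapses are rejected when they would break the edge link condition
// (non-manifold result) or flip an incident face normal, which keeps
// watertight inputs watertight.
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::array<double, 10> Quad; // symmetric 4x4: 11,12,13,14,22,23,24,33,34,44

inline Quad qzero() { Quad q; q.fill(0.0); return q; }
inline void qadd(Quad &a, const Quad &b) {
  for (int i = 0; i < 10; ++i) a[i] += b[i];
}
inline Quad qplane(double a, double b, double c, double d) {
  return Quad{a * a, a * b, a * c, a * d, b * b, b * c, b * d, c * c, c * d, d * d};
}
inline double qeval(const Quad &q, const double *p) {
  double x = p[0], y = p[1], z = p[2];
  return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
         q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y + q[7] * z * z +
         2 * q[8] * z + q[9];
}

struct Mesh {
  std::vector<std::array<double, 3>> V;
  std::vector<std::array<int, 3>> F;
  std::vector<bool> fdead;
  std::vector<std::vector<int>> vf; // incident alive faces per vertex
  std::vector<Quad> Q;

  void face_plane(int f, double *n, double &d, double &area) const {
    const auto &a = V[F[f][0]], &b = V[F[f][1]], &c = V[F[f][2]];
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double w[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    n[0] = u[1] * w[2] - u[2] * w[1];
    n[1] = u[2] * w[0] - u[0] * w[2];
    n[2] = u[0] * w[1] - u[1] * w[0];
    double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    area = 0.5 * nn;
    if (nn > 1e-300) { n[0] /= nn; n[1] /= nn; n[2] /= nn; }
    d = -(n[0] * a[0] + n[1] * a[1] + n[2] * a[2]);
  }

  void init_quadrics() {
    Q.assign(V.size(), qzero());
    for (size_t f = 0; f < F.size(); ++f) {
      double n[3], d, area;
      face_plane((int)f, n, d, area);
      Quad k = qplane(n[0], n[1], n[2], d);
      for (int i = 0; i < 10; ++i) k[i] *= area;
      for (int s = 0; s < 3; ++s) qadd(Q[F[f][s]], k);
    }
  }

  void neighbors(int v, std::set<int> &out) const {
    out.clear();
    for (int f : vf[v]) {
      if (fdead[f]) continue;
      for (int s = 0; s < 3; ++s)
        if (F[f][s] != v) out.insert(F[f][s]);
    }
  }

  // would moving vertex v to p flip any incident face not touching u?
  bool flips(int v, int skip, const double *p) const {
    for (int f : vf[v]) {
      if (fdead[f]) continue;
      const auto &tf = F[f];
      if (tf[0] == skip || tf[1] == skip || tf[2] == skip) continue;
      double before[3], after[3];
      std::array<double, 3> pa[3];
      for (int s = 0; s < 3; ++s) pa[s] = V[tf[s]];
      auto cr = [](const std::array<double, 3> &a, const std::array<double, 3> &b,
                   const std::array<double, 3> &c, double *n) {
        double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
        double w[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
        n[0] = u[1] * w[2] - u[2] * w[1];
        n[1] = u[2] * w[0] - u[0] * w[2];
        n[2] = u[0] * w[1] - u[1] * w[0];
      };
      cr(pa[0], pa[1], pa[2], before);
      for (int s = 0; s < 3; ++s)
        if (tf[s] == v) pa[s] = {p[0], p[1], p[2]};
      cr(pa[0], pa[1], pa[2], after);
      double dp = before[0] * after[0] + before[1] * after[1] + before[2] * after[2];
      double na = std::sqrt(after[0] * after[0] + after[1] * after[1] + after[2] * after[2]);
      double nb = std::sqrt(before[0] * before[0] + before[1] * before[1] + before[2] * before[2]);
      if (na < 1e-14 || nb < 1e-14) return true;
      if (dp / (na * nb) < 0.1) return true;
    }
    return false;
  }
};

// optimal collapse point for quadric q; fallback candidates if singular
void optimal_point(const Quad &q, const double *a, const double *b, double *out) {
  double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
  double rhs[3] = {-q[3], -q[6], -q[8]};
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
               A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
               A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) > 1e-12) {
    // Cramer
    auto d3 = [&](int col) {
      double M[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) M[i][j] = (j == col) ? rhs[i] : A[i][j];
      return M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
             M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
             M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    };
    out[0] = d3(0) / det; out[1] = d3(1) / det; out[2] = d3(2) / det;
    return;
  }
  double mid[3] = {(a[0] + b[0]) / 2, (a[1] + b[1]) / 2, (a[2] + b[2]) / 2};
  const double *cands[3] = {a, b, mid};
  double best = R_PosInf;
  for (int c = 0; c < 3; ++c) {
    double e = qeval(q, cands[c]);
    if (e < best) { best = e; out[0] = cands[c][0]; out[1] = cands[c][1]; out[2] = cands[c][2]; }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_simplify(NumericMatrix Vin, IntegerMatrix Fin, int target_faces,
                  int max_passes) {
  Mesh M;
  int nv = Vin.nrow(), nf = Fin.nrow();
  M.V.resize(nv);
  for (int i = 0; i < nv; ++i) M.V[i] = {Vin(i, 0), Vin(i, 1), Vin(i, 2)};
  M.F.resize(nf);
  for (int f = 0; f < nf; ++f) M.F[f] = {Fin(f, 0) - 1, Fin(f, 1) - 1, Fin(f, 2) - 1};
  M.fdead.assign(nf, false);
  M.vf.assign(nv, {});
  for (int f = 0; f < nf; ++f)
    for (int s = 0; s < 3; ++s) M.vf[M.F[f][s]].push_back(f);
  M.init_quadrics();

  int alive = nf;
  std::vector<bool> dirty(nv, false);
  std::set<int> nu, nvset;

  for (int pass = 0; pass < max_passes && alive > target_faces; ++pass) {
    double threshold = 1e-9 * std::pow((double)(pass + 3), 7.0);
    std::fill(dirty.begin(), dirty.end(), false);
    for (int f = 0; f < nf && alive > target_faces; ++f) {
      if (M.fdead[f]) continue;
      for (int s = 0; s < 3 && alive > target_faces; ++s) {
        int u = M.F[f][s], v = M.F[f][(s + 1) % 3];
        if (u == v || dirty[u] || dirty[v]) continue;
        Quad q = M.Q[u];
        qadd(q, M.Q[v]);
        double p[3];
        optimal_point(q, M.V[u].data(), M.V[v].data(), p);
        double err = qeval(q, p);
        if (err > threshold) continue;

        // link condition: exactly two shared neighbours for an interior edge
        M.neighbors(u, nu);
        M.neighbors(v, nvset);
        int shared = 0;
        for (int w : nu) if (nvset.count(w)) ++shared;
        if (shared != 2) continue;
        if (M.flips(u, v, p) || M.flips(v, u, p)) continue;

        // collapse v into u at p
        M.V[u] = {p[0], p[1], p[2]};
        M.Q[u] = q;
        for (int g : M.vf[v]) {
          if (M.fdead[g]) continue;
          auto &tf = M.F[g];
          bool hasu = (tf[0] == u || tf[1] == u || tf[2] == u);
          if (hasu) {
            M.fdead[g] = true;
            --alive;
          } else {
            for (int t = 0; t < 3; ++t)
              if (tf[t] == v) tf[t] = u;
            M.vf[u].push_back(g);
          }
        }
        M.vf[v].clear();
        dirty[u] = true;
        for (int w : nu) dirty[w] = true;
        for (int w : nvset) dirty[w] = true;
        break; // face may be dead now; move on
      }
    }
  }

  // compact
  std::vector<int> vmap(nv, -1);
  std::vector<std::array<int, 3>> FO;
  for (int f = 0; f < nf; ++f) {
    if (M.fdead[f]) continue;
    FO.push_back(M.F[f]);
    for (int s = 0; s < 3; ++s) vmap[M.F[f][s]] = 0;
  }
  int nvo = 0;
  for (int i = 0; i < nv; ++i)
    if (vmap[i] == 0) vmap[i] = nvo++;
  NumericMatrix VO(nvo, 3);
  for (int i = 0; i < nv; ++i)
    if (vmap[i] >= 0) {
      VO(vmap[i], 0) = M.V[i][0]; VO(vmap[i], 1) = M.V[i][1]; VO(vmap[i], 2) = M.V[i][2];
    }
  IntegerMatrix FOM((int)FO.size(), 3);
  for (size_t f = 0; f < FO.size(); ++f)
    for (int s = 0; s < 3; ++s) FOM((int)f, s) = vmap[FO[f][s]] + 1;
  return List::create(_["vertices"] = VO, _["faces"] = FOM);
}
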