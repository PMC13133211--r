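// Marching cubes on a scalar lattice. Per straddling cube the cut edges
// are paired on each cube face (4-cut ambiguous faces resolved by the
// bilinear asymptotic decider, which depends only on the shared face
// values and is therefore consistent between neighbouring cubes), traced
// into closed loops, oriented against the local field gradient (inside =
// value >= tau, normals outward) and fan-triangulated. Isosurface
// vertices sit on lattice edges and are welded by a global edge key, so
// the mesh is watertight by construction wherever the isosurface closes.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// corner c has offsets (c&1, (c>>1)&1, (c>>2)&1)
const int EDGE_CORNERS[12][2] = {
  {0, 1}, {2, 3}, {4, 5}, {6, 7},   // x-edges 0..3
  {0, 2}, {1, 3}, {4, 6}, {5, 7},   // y-edges 4..7
  {0, 4}, {1, 5}, {2, 6}, {3, 7}};  // z-edges 8..11
const int EDGE_AXIS[12] = {0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2};

// faces as cyclic corner quadruples
const int FACE_CORNERS[6][4] = {
  {0, 2, 6, 4},  // x-
  {1, 3, 7, 5},  // x+
  {0, 1, 5, 4},  // y-
  {2, 3, 7, 6},  // y+
  {0, 1, 3, 2},  // z-
  {4, 5, 7, 6}}; // z+

int edge_of_pair(int a, int b) {
  for (int e = 0; e < 12; ++e) {
    if ((EDGE_CORNERS[e][0] == a && EDGE_CORNERS[e][1] == b) ||
        (EDGE_CORNERS[e][0] == b && EDGE_CORNERS[e][1] == a))
      return e;
  }
  return -1;
}

} // namespace

// [[Rcpp::export]]
List cpp_marching_cubes(NumericVector vals, IntegerVector dims,
                        NumericVector origin, double pitch, double tau) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = vals.begin();
  auto lin = [&](int i, int j, int k) -> int64_t {
    return i + (int64_t)nx * (j + (int64_t)ny * k);
  };

  // face edge table: face f, slot s -> cube edge id between cyclic
  // corners s and s+1
  static int FACE_EDGE[6][4];
  static bool init = false;
  if (!init) {
    for (int f = 0; f < 6; ++f)
      for (int s = 0; s < 4; ++s)
        FACE_EDGE[f][s] =
            edge_of_pair(FACE_CORNERS[f][s], FACE_CORNERS[f][(s + 1) % 4]);
    init = true;
  }

  std::vector<double> verts;
  std::vector<int> tris;
  std::unordered_map<int64_t, int> weld;

  double cv[8];
  bool in[8];
  int evid[12];    // global vertex id per cut cube edge, -1 otherwise
  int link[12][2]; // loop adjacency between cut edges

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          cv[c] = v[lin(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1))];
          in[c] = cv[c] >= tau;
          nin += in[c];
        }
        if (nin == 0 || nin == 8) continue;

        for (int e = 0; e < 12; ++e) {
          evid[e] = -1;
          link[e][0] = link[e][1] = -1;
        }

        // welded vertex per cut edge
        for (int e = 0; e < 12; ++e) {
          int a = EDGE_CORNERS[e][0], b = EDGE_CORNERS[e][1];
          if (in[a] == in[b]) continue;
          int ax = EDGE_AXIS[e];
          int ia = i + (a & 1), ja = j + ((a >> 1) & 1), ka = k + ((a >> 2) & 1);
          int64_t key = lin(ia, ja, ka) * 3 + ax;
          auto it = weld.find(key);
          if (it != weld.end()) {
            evid[e] = it->second;
          } else {
            double t = (tau - cv[a]) / (cv[b] - cv[a]);
            double p[3] = {origin[0] + ia * pitch, origin[1] + ja * pitch,
                           origin[2] + ka * pitch};
            p[ax] += t * pitch;
            int id = (int)(verts.size() / 3);
            verts.push_back(p[0]); verts.push_back(p[1]); verts.push_back(p[2]);
            weld[key] = id;
            evid[e] = id;
          }
        }

        // pair cut edges on each face
        for (int f = 0; f < 6; ++f) {
          int cut[4], ncut = 0;
          for (int s = 0; s < 4; ++s)
            if (evid[FACE_EDGE[f][s]] >= 0) cut[ncut++] = s;
          if (ncut == 0) continue;
          auto add_link = [&](int sa, int sb) {
            int ea = FACE_EDGE[f][sa], eb = FACE_EDGE[f][sb];
            link[ea][link[ea][0] < 0 ? 0 : 1] = eb;
            link[eb][link[eb][0] < 0 ? 0 : 1] = ea;
          };
          if (ncut == 2) {
            add_link(cut[0], cut[1]);
          } else { // 4 cuts: corners alternate; asymptotic decider
            double f0 = cv[FACE_CORNERS[f][0]] - tau;
            double f1 = cv[FACE_CORNERS[f][1]] - tau;
            double f2 = cv[FACE_CORNERS[f][2]] - tau;
            double f3 = cv[FACE_CORNERS[f][3]] - tau;
            double den = f0 - f1 + f2 - f3;
            double saddle = (std::fabs(den) > 1e-300)
                                ? (f0 * f2 - f1 * f3) / den : 0.0;
            bool inside_connected = saddle >= 0.0; // saddle of (v - tau)
            // pair the two cut edges flanking each isolated corner
            for (int s = 0; s < 4; ++s) {
              bool corner_in = in[FACE_CORNERS[f][s]];
              bool isolated = inside_connected ? !corner_in : corner_in;
              if (isolated) add_link((s + 3) % 4, s);
            }
          }
        }

        // local field gradient (sign only matters)
        double g[3] = {0, 0, 0};
        for (int e = 0; e < 12; ++e)
          g[EDGE_AXIS[e]] += cv[EDGE_CORNERS[e][1]] - cv[EDGE_CORNERS[e][0]];

        // trace loops and emit fans
        bool used[12] = {false};
        for (int e0 = 0; e0 < 12; ++e0) {
          if (evid[e0] < 0 || used[e0]) continue;
          int loop[12], n = 0;
          int cur = e0, prev = -1;
          do {
            loop[n++] = cur;
            used[cur] = true;
            int nxt = (link[cur][0] != prev) ? link[cur][0] : link[cur][1];
            prev = cur;
            cur = nxt;
          } while (cur != e0 && cur >= 0 && n < 12);
          if (n < 3) continue;

          // Newell normal from actual vertex positions
          double nrm[3] = {0, 0, 0};
          for (int s = 0; s < n; ++s) {
            const double *pa = &verts[3 * evid[loop[s]]];
            const double *pb = &verts[3 * evid[loop[(s + 1) % n]]];
            nrm[0] += (pa[1] - pb[1]) * (pa[2] + pb[2]);
            nrm[1] += (pa[2] - pb[2]) * (pa[0] + pb[0]);
            nrm[2] += (pa[0] - pb[0]) * (pa[1] + pb[1]);
          }
          double dotg = nrm[0] * g[0] + nrm[1] * g[1] + nrm[2] * g[2];
          bool flip = dotg > 0; // outward normal points down-gradient
          for (int s = 1; s + 1 < n; ++s) {
            int a = evid[loop[0]];
            int b = evid[loop[flip ? s + 1 : s]];
            int c = evid[loop[flip ? s : s + 1]];
            tris.push_back(a); tris.push_back(b); tris.push_back(c);
          }
        }
      }

  int nvert = (int)(verts.size() / 3), ntri = (int)(tris.size() / 3);
  NumericMatrix VM(nvert, 3);
  for (int t = 0; t < nvert; ++t) {
    VM(t, 0) = verts[3 * t]; VM(t, 1) = verts[3 * t + 1]; VM(t, 2) = verts[3 * t + 2];
  }
  IntegerMatrix FM(ntri, 3);
  for (int t = 0; t < ntri; ++t) {
    FM(t, 0) = tris[3 * t] + 1; FM(t, 1) = tris[3 * t + 1] + 1; FM(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = VM, _["faces"] = FM);
}
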