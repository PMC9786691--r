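#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra. Each grid cube is split into
// six tetrahedra around the main diagonal; the split uses the same face
// diagonals on both sides of every cube face, so the resulting triangle mesh
// is watertight for any level set that stays inside the grid. Within a
// tetrahedron the field is linear, so triangles are oriented with the (exact)
// per-tet gradient: outward normals point from high values (inside) to low.

struct V3 { double x, y, z; };

static inline V3 sub(const V3& a, const V3& b) {
  return V3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 cross(const V3& a, const V3& b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
}
static inline double dot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// corner bit order: bit0 -> +x, bit1 -> +y, bit2 -> +z
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    double level) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t s1 = d0, s2 = (R_xlen_t)d0 * d1;
  uint64_t ntot = (uint64_t)d0 * d1 * d2;

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  vmap.reserve(1 << 16);

  double cv[8];
  uint64_t cid[8];
  V3 cp[8];

  // nudge values exactly at the level so no surface vertex lands on a node
  const double nudge = 1e-9 * (std::abs(level) > 0 ? std::abs(level) : 1.0);

  auto edge_vertex = [&](int a, int b) -> int {
    uint64_t ia = cid[a], ib = cid[b];
    uint64_t key = (ia < ib) ? ia * ntot + ib : ib * ntot + ia;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double va = cv[a], vb = cv[b];
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    // interpolate in a fixed node order so the position is bit-identical
    // regardless of which tetrahedron creates the vertex
    if (ia > ib) { t = 1.0 - t; std::swap(a, b); }
    V3 p{cp[a].x + t * (cp[b].x - cp[a].x),
         cp[a].y + t * (cp[b].y - cp[a].y),
         cp[a].z + t * (cp[b].z - cp[a].z)};
    int id = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    vmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int e0, int e1, int e2, const V3& grad) {
    V3 p0{vx[e0], vy[e0], vz[e0]};
    V3 p1{vx[e1], vy[e1], vz[e1]};
    V3 p2{vx[e2], vy[e2], vz[e2]};
    V3 n = cross(sub(p1, p0), sub(p2, p0));
    if (dot(n, grad) > 0) std::swap(e1, e2);
    tri.push_back(e0); tri.push_back(e1); tri.push_back(e2);
  };

  for (int k = 0; k < d2 - 1; k++)
    for (int j = 0; j < d1 - 1; j++)
      for (int i = 0; i < d0 - 1; i++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          R_xlen_t lin = ci + s1 * cj + s2 * ck;
          double v = field[lin];
          if (v == level) v = level - nudge;
          cv[c] = v;
          cid[c] = (uint64_t)lin;
          cp[c] = V3{origin[0] + spacing[0] * ci,
                     origin[1] + spacing[1] * cj,
                     origin[2] + spacing[2] * ck};
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; t++) {
          const int* T = TETS[t];
          int in[4], nin = 0;
          for (int c = 0; c < 4; c++) in[c] = cv[T[c]] > level ? 1 : 0;
          for (int c = 0; c < 4; c++) nin += in[c];
          if (nin == 0 || nin == 4) continue;

          // linear gradient of the field on this tet (solve 3x3)
          V3 e1 = sub(cp[T[1]], cp[T[0]]);
          V3 e2 = sub(cp[T[2]], cp[T[0]]);
          V3 e3 = sub(cp[T[3]], cp[T[0]]);
          double f1 = cv[T[1]] - cv[T[0]];
          double f2 = cv[T[2]] - cv[T[0]];
          double f3 = cv[T[3]] - cv[T[0]];
          // grad = A^{-T} f where rows of A are e1,e2,e3; use cofactors
          V3 c23 = cross(e2, e3), c31 = cross(e3, e1), c12 = cross(e1, e2);
          double det = dot(e1, c23);
          V3 grad{(c23.x * f1 + c31.x * f2 + c12.x * f3) / det,
                  (c23.y * f1 + c31.y * f2 + c12.y * f3) / det,
                  (c23.z * f1 + c31.z * f2 + c12.z * f3) / det};

          if (nin == 1 || nin == 3) {
            int a = -1;
            for (int c = 0; c < 4; c++)
              if ((nin == 1 && in[c]) || (nin == 3 && !in[c])) a = c;
            int o[3], m = 0;
            for (int c = 0; c < 4; c++) if (c != a) o[m++] = c;
            int ea = edge_vertex(T[a], T[o[0]]);
            int eb = edge_vertex(T[a], T[o[1]]);
            int ec = edge_vertex(T[a], T[o[2]]);
            emit(ea, eb, ec, grad);
          } else {
            int a = -1, b = -1, c1 = -1, c2 = -1;
            for (int c = 0; c < 4; c++) {
              if (in[c]) { if (a < 0) a = c; else b = c; }
              else { if (c1 < 0) c1 = c; else c2 = c; }
            }
            int eac = edge_vertex(T[a], T[c1]);
            int ead = edge_vertex(T[a], T[c2]);
            int ebd = edge_vertex(T[b], T[c2]);
            int ebc = edge_vertex(T[b], T[c1]);
            emit(eac, ead, ebd, grad);
            emit(eac, ebd, ebc, grad);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)(tri.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; v++) {
    verts(v, 0) = vx[v]; verts(v, 1) = vy[v]; verts(v, 2) = vz[v];
  }
  IntegerMatrix faces(nf, 3);
  for (int f = 0; f < nf; f++) {
    faces(f, 0) = tri[3 * f] + 1;
    faces(f, 1) = tri[3 * f + 1] + 1;
    faces(f, 2) = tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
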