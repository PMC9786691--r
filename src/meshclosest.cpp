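#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact closest point on a triangle mesh for a batch of query points.
// Triangles are binned into a uniform grid by bounding box; queries expand
// Chebyshev rings of cells outward and prune cells whose box distance
// exceeds the current best, which makes the result exact (not k-NN
// approximate). Distances are point-to-triangle, never point-to-vertex.

struct P3 { double x, y, z; };

static inline P3 psub(const P3& a, const P3& b) {
  return P3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double pdot(const P3& a, const P3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Ericson, Real-Time Collision Detection, closest point on triangle.
static P3 closest_on_tri(const P3& p, const P3& a, const P3& b, const P3& c) {
  P3 ab = psub(b, a), ac = psub(c, a), ap = psub(p, a);
  double d1 = pdot(ab, ap), d2 = pdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  P3 bp = psub(p, b);
  double d3 = pdot(ab, bp), d4 = pdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return P3{a.x + v * ab.x, a.y + v * ab.y, a.z + v * ab.z};
  }
  P3 cp = psub(p, c);
  double d5 = pdot(ab, cp), d6 = pdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return P3{a.x + w * ac.x, a.y + w * ac.y, a.z + w * ac.z};
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    P3 bc = psub(c, b);
    return P3{b.x + w * bc.x, b.y + w * bc.y, b.z + w * bc.z};
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return P3{a.x + ab.x * v + ac.x * w, a.y + ab.y * v + ac.y * w,
            a.z + ab.z * v + ac.z * w};
}

// [[Rcpp::export(name = ".mesh_closest_cpp")]]
List mesh_closest_cpp(NumericMatrix verts, IntegerMatrix faces,
                      NumericMatrix query) {
  int nf = faces.nrow(), nq = query.nrow();
  std::vector<P3> A(nf), B(nf), C(nf);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int f = 0; f < nf; f++) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    A[f] = P3{verts(ia, 0), verts(ia, 1), verts(ia, 2)};
    B[f] = P3{verts(ib, 0), verts(ib, 1), verts(ib, 2)};
    C[f] = P3{verts(ic, 0), verts(ic, 1), verts(ic, 2)};
    const P3* ps[3] = {&A[f], &B[f], &C[f]};
    for (int s = 0; s < 3; s++) {
      const double q[3] = {ps[s]->x, ps[s]->y, ps[s]->z};
      for (int d = 0; d < 3; d++) {
        if (q[d] < lo[d]) lo[d] = q[d];
        if (q[d] > hi[d]) hi[d] = q[d];
      }
    }
  }
  double ext[3];
  for (int d = 0; d < 3; d++) {
    ext[d] = hi[d] - lo[d];
    if (ext[d] <= 0) ext[d] = 1e-9;
  }
  double vol = ext[0] * ext[1] * ext[2];
  double h = std::cbrt(vol / std::max(nf / 4.0, 1.0));
  int g[3];
  for (int d = 0; d < 3; d++) {
    g[d] = std::max(1, std::min(192, (int)std::ceil(ext[d] / h)));
  }
  double cs[3];
  for (int d = 0; d < 3; d++) cs[d] = ext[d] / g[d];
  double csmall = std::min(cs[0], std::min(cs[1], cs[2]));

  // bin triangles by bbox
  std::vector<std::vector<int>> cells((size_t)g[0] * g[1] * g[2]);
  for (int f = 0; f < nf; f++) {
    double tlo[3], thi[3];
    const P3* ps[3] = {&A[f], &B[f], &C[f]};
    for (int d = 0; d < 3; d++) { tlo[d] = R_PosInf; thi[d] = R_NegInf; }
    for (int s = 0; s < 3; s++) {
      const double q[3] = {ps[s]->x, ps[s]->y, ps[s]->z};
      for (int d = 0; d < 3; d++) {
        if (q[d] < tlo[d]) tlo[d] = q[d];
        if (q[d] > thi[d]) thi[d] = q[d];
      }
    }
    int c0[3], c1[3];
    for (int d = 0; d < 3; d++) {
      c0[d] = std::max(0, std::min(g[d] - 1, (int)((tlo[d] - lo[d]) / cs[d])));
      c1[d] = std::max(0, std::min(g[d] - 1, (int)((thi[d] - lo[d]) / cs[d])));
    }
    for (int ck = c0[2]; ck <= c1[2]; ck++)
      for (int cj = c0[1]; cj <= c1[1]; cj++)
        for (int ci = c0[0]; ci <= c1[0]; ci++)
          cells[(size_t)ci + (size_t)g[0] * (cj + (size_t)g[1] * ck)]
              .push_back(f);
  }

  std::vector<int> stamp(nf, -1);
  NumericVector dist(nq);
  NumericMatrix cpts(nq, 3);
  IntegerVector tidx(nq);
  int maxg = std::max(g[0], std::max(g[1], g[2]));

  for (int q = 0; q < nq; q++) {
    P3 p{query(q, 0), query(q, 1), query(q, 2)};
    int base[3];
    const double pq[3] = {p.x, p.y, p.z};
    for (int d = 0; d < 3; d++) {
      base[d] = std::max(0, std::min(g[d] - 1,
                                     (int)((pq[d] - lo[d]) / cs[d])));
    }
    double best = R_PosInf;
    P3 bestp{0, 0, 0};
    int bestf = -1;

    for (int r = 0; r <= maxg; r++) {
      double ring_min = R_PosInf;
      bool any_cell = false;
      int i0 = base[0] - r, i1 = base[0] + r;
      int j0 = base[1] - r, j1 = base[1] + r;
      int k0 = base[2] - r, k1 = base[2] + r;
      for (int ck = k0; ck <= k1; ck++) {
        if (ck < 0 || ck >= g[2]) continue;
        for (int cj = j0; cj <= j1; cj++) {
          if (cj < 0 || cj >= g[1]) continue;
          for (int ci = i0; ci <= i1; ci++) {
            if (ci < 0 || ci >= g[0]) continue;
            int cheb = std::max(std::abs(ci - base[0]),
                                std::max(std::abs(cj - base[1]),
                                         std::abs(ck - base[2])));
            if (cheb != r) continue;
            any_cell = true;
            // box distance from p to this cell
            double bd2 = 0;
            double cl[3] = {lo[0] + ci * cs[0], lo[1] + cj * cs[1],
                            lo[2] + ck * cs[2]};
            double chg[3] = {cl[0] + cs[0], cl[1] + cs[1], cl[2] + cs[2]};
            for (int d = 0; d < 3; d++) {
              double v = pq[d];
              double e = (v < cl[d]) ? (cl[d] - v)
                                     : ((v > chg[d]) ? v - chg[d] : 0.0);
              bd2 += e * e;
            }
            double bd = std::sqrt(bd2);
            if (bd < ring_min) ring_min = bd;
            if (bd >= best) continue;
            const std::vector<int>& cell =
                cells[(size_t)ci + (size_t)g[0] * (cj + (size_t)g[1] * ck)];
            for (size_t m = 0; m < cell.size(); m++) {
              int f = cell[m];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              P3 cp = closest_on_tri(p, A[f], B[f], C[f]);
              P3 dv = psub(p, cp);
              double dd = std::sqrt(pdot(dv, dv));
              if (dd < best) { best = dd; bestp = cp; bestf = f; }
            }
          }
        }
      }
      // shells are nested boxes around the base cell, so the minimum box
      // distance over a shell is nondecreasing in r: safe to stop
      if (!any_cell) break;                       // grid exhausted
      if (bestf >= 0 && ring_min > best) break;
    }
    (void)csmall;
    dist[q] = best;
    cpts(q, 0) = bestp.x; cpts(q, 1) = bestp.y; cpts(q, 2) = bestp.z;
    tidx[q] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = cpts,
                      _["face"] = tidx);
}
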