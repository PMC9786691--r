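#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable over the three axes with anisotropic
// voxel spacing. Input: binary feature mask; output: distance in world units
// from each voxel centre to the nearest feature voxel centre (0 inside).

static const double BIG = 1e30;

// 1D squared distance transform along a line of n samples with spacing w.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int maxd = std::max(d0, std::max(d1, d2));
  std::vector<double> line(maxd), res(maxd);
  std::vector<int> v(maxd);
  std::vector<double> z(maxd + 1);

  // pass along x (stride 1)
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++) {
      double* p = &out[(R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
      dt1d(p, res.data(), d0, spacing[0], v, z);
      std::copy(res.begin(), res.begin() + d0, p);
    }
  // pass along y (stride d0)
  for (int k = 0; k < d2; k++)
    for (int i = 0; i < d0; i++) {
      R_xlen_t base = i + (R_xlen_t)d0 * d1 * k;
      for (int j = 0; j < d1; j++) line[j] = out[base + (R_xlen_t)d0 * j];
      dt1d(line.data(), res.data(), d1, spacing[1], v, z);
      for (int j = 0; j < d1; j++) out[base + (R_xlen_t)d0 * j] = res[j];
    }
  // pass along z (stride d0*d1)
  R_xlen_t sz = (R_xlen_t)d0 * d1;
  for (int j = 0; j < d1; j++)
    for (int i = 0; i < d0; i++) {
      R_xlen_t base = i + (R_xlen_t)d0 * j;
      for (int k = 0; k < d2; k++) line[k] = out[base + sz * k];
      dt1d(line.data(), res.data(), d2, spacing[2], v, z);
      for (int k = 0; k < d2; k++) out[base + sz * k] = res[k];
    }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (out[i] >= BIG) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// Trilinear interpolation of a 3D volume at continuous 0-based voxel
// coordinates. Points outside the grid return `outside`.
// [[Rcpp::export(name = ".interp_trilinear_cpp")]]
NumericVector interp_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix idx, double outside) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t np = idx.nrow();
  NumericVector out(np);
  R_xlen_t s1 = d0, s2 = (R_xlen_t)d0 * d1;
  for (R_xlen_t p = 0; p < np; p++) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 &&
          x <= d0 - 1 && y <= d1 - 1 && z <= d2 - 1)) {
      out[p] = outside;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 >= d0 - 1) i0 = d0 - 2;
    if (j0 >= d1 - 1) j0 = d1 - 2;
    if (k0 >= d2 - 1) k0 = d2 - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    R_xlen_t b = i0 + s1 * j0 + s2 * k0;
    double c000 = vol[b],           c100 = vol[b + 1];
    double c010 = vol[b + s1],      c110 = vol[b + 1 + s1];
    double c001 = vol[b + s2],      c101 = vol[b + 1 + s2];
    double c011 = vol[b + s1 + s2], c111 = vol[b + 1 + s1 + s2];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
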