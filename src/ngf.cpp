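#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused NGF objective: for each masked fixed-grid point, map it through the
// affine (fixed -> moving), sample the three moving-gradient volumes with
// trilinear interpolation, rotate the gradient back (chain rule) and
// accumulate the NGF integrand against the fixed gradient.
// [[Rcpp::export(name = ".ngf_value_cpp")]]
double ngf_value_cpp(NumericMatrix X, NumericMatrix GF,
                     NumericVector gx, NumericVector gy, NumericVector gz,
                     IntegerVector dim, NumericVector spacing,
                     NumericVector origin, NumericMatrix A,
                     double eps, double voxvol) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t s1 = d0, s2 = (R_xlen_t)d0 * d1;
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  double e2 = eps * eps;
  double acc = 0;
  R_xlen_t n = X.nrow();
  const double* Xp = REAL(X);
  const double* Fp = REAL(GF);
  const double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const double* gzp = REAL(gz);
  for (R_xlen_t p = 0; p < n; p++) {
    double wx = Xp[p], wy = Xp[p + n], wz = Xp[p + 2 * n];
    double mx = a00 * wx + a01 * wy + a02 * wz + a03;
    double my = a10 * wx + a11 * wy + a12 * wz + a13;
    double mz = a20 * wx + a21 * wy + a22 * wz + a23;
    double x = (mx - origin[0]) / spacing[0];
    double y = (my - origin[1]) / spacing[1];
    double z = (mz - origin[2]) / spacing[2];
    double g0 = 0, g1 = 0, g2 = 0;
    if (x >= 0 && y >= 0 && z >= 0 &&
        x <= d0 - 1 && y <= d1 - 1 && z <= d2 - 1) {
      int i0 = (int)x, j0 = (int)y, k0 = (int)z;
      if (i0 >= d0 - 1) i0 = d0 - 2;
      if (j0 >= d1 - 1) j0 = d1 - 2;
      if (k0 >= d2 - 1) k0 = d2 - 2;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      R_xlen_t b = i0 + s1 * j0 + s2 * k0;
      double w000 = (1 - fx) * (1 - fy) * (1 - fz);
      double w100 = fx * (1 - fy) * (1 - fz);
      double w010 = (1 - fx) * fy * (1 - fz);
      double w110 = fx * fy * (1 - fz);
      double w001 = (1 - fx) * (1 - fy) * fz;
      double w101 = fx * (1 - fy) * fz;
      double w011 = (1 - fx) * fy * fz;
      double w111 = fx * fy * fz;
      g0 = w000 * gxp[b] + w100 * gxp[b + 1] + w010 * gxp[b + s1] +
           w110 * gxp[b + 1 + s1] + w001 * gxp[b + s2] +
           w101 * gxp[b + 1 + s2] + w011 * gxp[b + s1 + s2] +
           w111 * gxp[b + 1 + s1 + s2];
      g1 = w000 * gyp[b] + w100 * gyp[b + 1] + w010 * gyp[b + s1] +
           w110 * gyp[b + 1 + s1] + w001 * gyp[b + s2] +
           w101 * gyp[b + 1 + s2] + w011 * gyp[b + s1 + s2] +
           w111 * gyp[b + 1 + s1 + s2];
      g2 = w000 * gzp[b] + w100 * gzp[b + 1] + w010 * gzp[b + s1] +
           w110 * gzp[b + 1 + s1] + w001 * gzp[b + s2] +
           w101 * gzp[b + 1 + s2] + w011 * gzp[b + s1 + s2] +
           w111 * gzp[b + 1 + s1 + s2];
    }
    // chain rule: grad_x M(Ax) = R^T grad M, i.e. row-vector times R
    double h0 = g0 * a00 + g1 * a10 + g2 * a20;
    double h1 = g0 * a01 + g1 * a11 + g2 * a21;
    double h2 = g0 * a02 + g1 * a12 + g2 * a22;
    double f0 = Fp[p], f1 = Fp[p + n], f2 = Fp[p + 2 * n];
    double num = f0 * h0 + f1 * h1 + f2 * h2 + e2;
    double den = std::sqrt(f0 * f0 + f1 * f1 + f2 * f2 + e2) *
                 std::sqrt(h0 * h0 + h1 * h1 + h2 * h2 + e2);
    double r = num / den;
    acc += 1.0 - r * r;
  }
  return acc * voxvol;
}
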