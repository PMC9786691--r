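#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable 1D convolution along one axis of a 3D array, with replicate or
// zero boundary handling. axis is 1, 2 or 3 (R convention).
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis, bool replicate) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int r = (kernel.size() - 1) / 2;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  const double* v = REAL(vol);
  double* o = REAL(out);
  const double* k = REAL(kernel);
  R_xlen_t stride, nline, len;
  if (axis == 1) { stride = 1; len = d0; }
  else if (axis == 2) { stride = d0; len = d1; }
  else { stride = (R_xlen_t)d0 * d1; len = d2; }
  std::vector<double> line(len);
  // iterate over all lines along the chosen axis
  int da = (axis == 1) ? d1 : d0;
  int db = (axis == 3) ? d1 : d2;
  for (int jb = 0; jb < db; jb++) {
    for (int ja = 0; ja < da; ja++) {
      R_xlen_t base;
      if (axis == 1) base = (R_xlen_t)d0 * ja + (R_xlen_t)d0 * d1 * jb;
      else if (axis == 2) base = ja + (R_xlen_t)d0 * d1 * jb;
      else base = ja + (R_xlen_t)d0 * jb;
      for (R_xlen_t t = 0; t < len; t++) line[t] = v[base + stride * t];
      for (R_xlen_t t = 0; t < len; t++) {
        double acc = 0;
        for (int m = -r; m <= r; m++) {
          R_xlen_t u = t + m;
          double val;
          if (u < 0) val = replicate ? line[0] : 0.0;
          else if (u >= len) val = replicate ? line[len - 1] : 0.0;
          else val = line[u];
          acc += k[m + r] * val;
        }
        o[base + stride * t] = acc;
      }
    }
  }
  (void)nline;
  return out;
}
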