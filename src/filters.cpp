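#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// reflecting boundary index
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int hw = (int)std::ceil(3.5 * sigma);
  if (hw < 1) hw = 1;
  std::vector<double> k(2 * hw + 1);
  double s = 0.0;
  for (int i = -hw; i <= hw; ++i) {
    k[i + hw] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + hw];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// Separable 3D Gaussian filter; sigma given per axis in voxel units.
// Axes with sigma <= 0 are left untouched.
// [[Rcpp::export]]
NumericVector cpp_sep_gauss3d(NumericVector vol, IntegerVector dim,
                              NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(clone(vol));
  std::vector<double> buf(std::max(std::max(nx, ny), nz));

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    std::vector<double> k = gauss_kernel(s);
    int hw = ((int)k.size() - 1) / 2;
    int len = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    // stride along the axis, number of lines
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? nx : (R_xlen_t)nx * ny;
    R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // compute base index of this line
      R_xlen_t base;
      if (ax == 0) {
        base = line * nx;
      } else if (ax == 1) {
        R_xlen_t x = line % nx, z = line / nx;
        base = x + (R_xlen_t)nx * ny * z;
      } else {
        base = line; // x + nx*y
      }
      for (int i = 0; i < len; ++i) buf[i] = out[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int j = -hw; j <= hw; ++j)
          acc += k[j + hw] * buf[reflect(i + j, len)];
        out[base + stride * i] = acc;
      }
    }
  }
  return out;
}
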