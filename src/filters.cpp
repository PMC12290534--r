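// Small 3D filters: separable convolution (SSIM local windows) and a 3x3x3
// median (the bundled reference denoise plugin). Mirror boundaries.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = std::abs(i) % p;
  return (i < n) ? i : p - i;
}

// [[Rcpp::export]]
NumericVector cpp_sep_conv3(NumericVector img, IntegerVector dim,
                            NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size();
  if (kn % 2 == 0) stop("kernel length must be odd");
  const int kh = kn / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(nvox);
  auto at = [&](std::vector<double>& v, int x, int y, int z) -> double& {
    return v[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        for (int k = -kh; k <= kh; ++k)
          s += kernel[k + kh] * at(a, mirror(x + k, nx), y, z);
        at(b, x, y, z) = s;
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        for (int k = -kh; k <= kh; ++k)
          s += kernel[k + kh] * at(b, x, mirror(y + k, ny), z);
        at(a, x, y, z) = s;
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        for (int k = -kh; k <= kh; ++k)
          s += kernel[k + kh] * at(a, x, y, mirror(z + k, nz));
        at(b, x, y, z) = s;
      }
  return NumericVector(b.begin(), b.end());
}

// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector img, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double buf[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int n = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx)
              buf[n++] = img[(R_xlen_t)mirror(z + dz, nz) * nx * ny +
                             (R_xlen_t)mirror(y + dy, ny) * nx +
                             mirror(x + dx, nx)];
        std::nth_element(buf, buf + 13, buf + 27);
        out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = buf[13];
      }
  return out;
}
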