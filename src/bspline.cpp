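// Separable B-spline resampling (orders 0-5) with mirror boundaries.
// Prefiltering follows the classic recursive causal/anticausal scheme so
// that interpolation reproduces the input exactly at grid points.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static int spline_poles(int order, double* poles) {
  switch (order) {
  case 0: case 1: return 0;
  case 2:
    poles[0] = std::sqrt(8.0) - 3.0; return 1;
  case 3:
    poles[0] = std::sqrt(3.0) - 2.0; return 1;
  case 4:
    poles[0] = std::sqrt(664.0 - std::sqrt(438976.0)) + std::sqrt(304.0) - 19.0;
    poles[1] = std::sqrt(664.0 + std::sqrt(438976.0)) - std::sqrt(304.0) - 19.0;
    return 2;
  case 5:
    poles[0] = std::sqrt(135.0 / 2.0 - std::sqrt(17745.0 / 4.0)) +
               std::sqrt(105.0 / 4.0) - 13.0 / 2.0;
    poles[1] = std::sqrt(135.0 / 2.0 + std::sqrt(17745.0 / 4.0)) -
               std::sqrt(105.0 / 4.0) - 13.0 / 2.0;
    return 2;
  default:
    Rcpp::stop("B-spline order must be in 0..5");
  }
  return 0;
}

static double initial_causal(const std::vector<double>& c, double z) {
  const int n = (int)c.size();
  double tol = 1e-10;
  int horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
  if (horizon < n) {
    double zn = z, sum = c[0];
    for (int k = 1; k < horizon; ++k) { sum += zn * c[k]; zn *= z; }
    return sum;
  }
  // full mirror-boundary sum
  double zn = z, iz = 1.0 / z, z2n = std::pow(z, (double)(n - 1));
  double sum = c[0] + z2n * c[n - 1];
  z2n *= z2n * iz;
  for (int k = 1; k <= n - 2; ++k) {
    sum += (zn + z2n) * c[k];
    zn *= z; z2n *= iz;
  }
  return sum / (1.0 - std::pow(z, (double)(2 * n - 2)));
}

static void prefilter_line(std::vector<double>& c, const double* poles, int np) {
  const int n = (int)c.size();
  if (n == 1) return;
  double gain = 1.0;
  for (int p = 0; p < np; ++p)
    gain *= (1.0 - poles[p]) * (1.0 - 1.0 / poles[p]);
  for (int k = 0; k < n; ++k) c[k] *= gain;
  for (int p = 0; p < np; ++p) {
    const double z = poles[p];
    c[0] = initial_causal(c, z);
    for (int k = 1; k < n; ++k) c[k] += z * c[k - 1];
    c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
    for (int k = n - 2; k >= 0; --k) c[k] = z * (c[k + 1] - c[k]);
  }
}

// mirror boundary without edge repetition (period 2n-2)
static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = std::abs(i) % p;
  return (i < n) ? i : p - i;
}

static void spline_weights(int order, double x, int* idx0, double* w) {
  double wf;
  int i;
  switch (order) {
  case 0:
    i = (int)std::floor(x + 0.5); *idx0 = i; w[0] = 1.0; return;
  case 1:
    i = (int)std::floor(x); *idx0 = i;
    w[1] = x - i; w[0] = 1.0 - w[1]; return;
  case 2:
    i = (int)std::floor(x + 0.5); *idx0 = i - 1;
    wf = x - i;
    w[1] = 0.75 - wf * wf;
    w[2] = 0.5 * (wf - w[1] + 1.0);
    w[0] = 1.0 - w[1] - w[2];
    return;
  case 3:
    i = (int)std::floor(x); *idx0 = i - 1;
    wf = x - i;
    w[3] = (1.0 / 6.0) * wf * wf * wf;
    w[0] = (1.0 / 6.0) + 0.5 * wf * (wf - 1.0) - w[3];
    w[2] = wf + w[0] - 2.0 * w[3];
    w[1] = 1.0 - w[0] - w[2] - w[3];
    return;
  case 4: {
    i = (int)std::floor(x + 0.5); *idx0 = i - 2;
    wf = x - i;
    double w2 = wf * wf;
    double t = (1.0 / 6.0) * w2;
    double a = 0.5 - wf;
    a *= a;
    w[0] = (1.0 / 24.0) * a * a;
    double t0 = wf * (t - 11.0 / 24.0);
    double t1 = 19.0 / 96.0 + w2 * (0.25 - t);
    w[1] = t1 + t0;
    w[3] = t1 - t0;
    w[4] = w[0] + t0 + 0.5 * wf;
    w[2] = 1.0 - w[0] - w[1] - w[3] - w[4];
    return;
  }
  case 5: {
    i = (int)std::floor(x); *idx0 = i - 2;
    wf = x - i;
    double w2 = wf * wf;
    w[5] = (1.0 / 120.0) * wf * w2 * w2;
    w2 -= wf;
    double w4 = w2 * w2;
    wf -= 0.5;
    double t = w2 * (w2 - 3.0);
    w[0] = (1.0 / 24.0) * (1.0 / 5.0 + w2 + w4) - w[5];
    double t0 = (1.0 / 24.0) * (w2 * (w2 - 5.0) + 46.0 / 5.0);
    double t1 = (-1.0 / 12.0) * wf * (t + 4.0);
    w[2] = t0 + t1;
    w[3] = t0 - t1;
    t0 = (1.0 / 16.0) * (9.0 / 5.0 - t);
    t1 = (1.0 / 24.0) * wf * (w4 - w2 - 5.0);
    w[1] = t0 + t1;
    w[4] = t0 - t1;
    return;
  }
  default:
    Rcpp::stop("B-spline order must be in 0..5");
  }
}

// [[Rcpp::export]]
NumericVector cpp_bspline_resample(NumericVector img, IntegerVector in_dim,
                                   NumericVector scale, IntegerVector out_dim,
                                   int order) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const R_xlen_t nin = (R_xlen_t)nx * ny * nz;
  if (img.size() != nin) stop("dimension mismatch");
  double poles[2];
  const int np = spline_poles(order, poles);
  const int nt = order + 1;  // support taps per axis

  // prefilter into interpolation coefficients, axis by axis
  std::vector<double> coef(img.begin(), img.end());
  if (np > 0) {
    std::vector<double> line;
    // x axis
    line.resize(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t off = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) line[x] = coef[off + x];
        prefilter_line(line, poles, np);
        for (int x = 0; x < nx; ++x) coef[off + x] = line[x];
      }
    // y axis
    line.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t off = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) line[y] = coef[off + (R_xlen_t)y * nx];
        prefilter_line(line, poles, np);
        for (int y = 0; y < ny; ++y) coef[off + (R_xlen_t)y * nx] = line[y];
      }
    // z axis
    line.resize(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t off = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z)
          line[z] = coef[off + (R_xlen_t)z * nx * ny];
        prefilter_line(line, poles, np);
        for (int z = 0; z < nz; ++z)
          coef[off + (R_xlen_t)z * nx * ny] = line[z];
      }
  }

  // per-axis tap indices and weights (corner-aligned mapping: out index j
  // sits at input index j * scale)
  std::vector<int> ix(ox * nt), iy(oy * nt), iz(oz * nt);
  std::vector<double> wx(ox * nt), wy(oy * nt), wz(oz * nt);
  auto fill_axis = [&](int nout, int nin_ax, double sc,
                       std::vector<int>& iv, std::vector<double>& wv) {
    double w[6];
    int i0;
    for (int j = 0; j < nout; ++j) {
      spline_weights(order, j * sc, &i0, w);
      for (int t = 0; t < nt; ++t) {
        iv[j * nt + t] = mirror_idx(i0 + t, nin_ax);
        wv[j * nt + t] = w[t];
      }
    }
  };
  fill_axis(ox, nx, scale[0], ix, wx);
  fill_axis(oy, ny, scale[1], iy, wy);
  fill_axis(oz, nz, scale[2], iz, wz);

  NumericVector out((R_xlen_t)ox * oy * oz);
  R_xlen_t o = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++o) {
        double acc = 0.0;
        for (int tz = 0; tz < nt; ++tz) {
          const R_xlen_t zoff = (R_xlen_t)iz[z * nt + tz] * nx * ny;
          const double wzt = wz[z * nt + tz];
          for (int ty = 0; ty < nt; ++ty) {
            const R_xlen_t yoff = zoff + (R_xlen_t)iy[y * nt + ty] * nx;
            const double wyt = wzt * wy[y * nt + ty];
            double accx = 0.0;
            for (int tx = 0; tx < nt; ++tx)
              accx += wx[x * nt + tx] * coef[yoff + ix[x * nt + tx]];
            acc += wyt * accx;
          }
        }
        out[o] = acc;
      }
  return out;
}
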