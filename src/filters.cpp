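#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing with reflected borders; sigma in voxels per axis.

static void conv1d_axis(std::vector<double> &vol, int nx, int ny, int nz,
                        int axis, const std::vector<double> &k) {
  const int kr = (int)(k.size() / 2);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : nxy);
  std::vector<double> line(n), res(n);
  int no = axis == 0 ? ny : nx;
  int nf = axis == 2 ? ny : nz;
  for (int b = 0; b < nf; ++b)
    for (int a = 0; a < no; ++a) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)b * nxy + (R_xlen_t)a * nx;
      else if (axis == 1) base = (R_xlen_t)b * nxy + a;
      else base = (R_xlen_t)b * nx + a;
      for (int i = 0; i < n; ++i) line[i] = vol[base + i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -kr; j <= kr; ++j) {
          int idx = i + j;
          if (idx < 0) idx = -idx - 1;            // reflect
          if (idx >= n) idx = 2 * n - idx - 1;
          acc += k[j + kr] * line[idx];
        }
        res[i] = acc;
      }
      for (int i = 0; i < n; ++i) vol[base + i * stride] = res[i];
    }
}

// [[Rcpp::export(name = ".gauss3d_cpp")]]
NumericVector gauss3d_cpp(NumericVector img, IntegerVector dim,
                          NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> vol(img.begin(), img.end());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int kr = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * kr + 1);
    double sum = 0.0;
    for (int j = -kr; j <= kr; ++j) {
      k[j + kr] = std::exp(-0.5 * j * j / (s * s));
      sum += k[j + kr];
    }
    for (double &v : k) v /= sum;
    conv1d_axis(vol, nx, ny, nz, axis, k);
  }
  return NumericVector(vol.begin(), vol.end());
}

// Non-local means on a 3D volume. Patch/search radii in voxels; h is the
// filter strength (intensity units). Weights w = exp(-d2 / h^2) with d2 the
// mean squared intensity difference over the (clipped) patch; the centre
// voxel gets the maximum weight seen among its neighbours, the usual device
// that avoids over-weighting the noisy self-comparison.
// [[Rcpp::export(name = ".nlm3d_cpp")]]
NumericVector nlm3d_cpp(NumericVector img, IntegerVector dim,
                        int patch_r, int search_r, double h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double h2 = h * h;
  const double *u = img.begin();

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t ci = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        double wsum = 0.0, acc = 0.0, wmax = 0.0;
        for (int dz = -search_r; dz <= search_r; ++dz) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -search_r; dy <= search_r; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -search_r; dx <= search_r; ++dx) {
              int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              // patch distance (clipped at borders, averaged over valid offsets)
              double d2 = 0.0; int cnt = 0;
              for (int pz = -patch_r; pz <= patch_r; ++pz) {
                int az = z + pz, bz = zz + pz;
                if (az < 0 || az >= nz || bz < 0 || bz >= nz) continue;
                for (int py = -patch_r; py <= patch_r; ++py) {
                  int ay = y + py, by = yy + py;
                  if (ay < 0 || ay >= ny || by < 0 || by >= ny) continue;
                  for (int px = -patch_r; px <= patch_r; ++px) {
                    int ax = x + px, bx = xx + px;
                    if (ax < 0 || ax >= nx || bx < 0 || bx >= nx) continue;
                    double diff = u[(R_xlen_t)az * nxy + (R_xlen_t)ay * nx + ax] -
                                  u[(R_xlen_t)bz * nxy + (R_xlen_t)by * nx + bx];
                    d2 += diff * diff;
                    ++cnt;
                  }
                }
              }
              if (cnt == 0) continue;
              double w = std::exp(-(d2 / cnt) / h2);
              if (w > wmax) wmax = w;
              wsum += w;
              acc += w * u[(R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx];
            }
          }
        }
        double wc = (wmax > 0.0) ? wmax : 1.0;
        out[ci] = (acc + wc * u[ci]) / (wsum + wc);
      }
  return out;
}
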