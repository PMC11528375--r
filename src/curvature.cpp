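#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Per-vertex principal curvatures by local quadric fits over all mesh
// vertices within a physical patch radius (uniform-grid neighbour search).
// The local height over the tangent plane is fit as
// h = a u^2/2 + b u w + c w^2/2 + d u + e w; principal curvatures are the
// eigenvalues of -[[a, b], [b, c]] (positive = locally convex w.r.t. the
// outward normal).

static bool solve5(double A[5][5], double b[5], double x[5]) {
  int idx[5] = {0, 1, 2, 3, 4};
  for (int col = 0; col < 5; ++col) {
    int piv = col;
    for (int r = col + 1; r < 5; ++r)
      if (std::fabs(A[idx[r]][col]) > std::fabs(A[idx[piv]][col])) piv = r;
    std::swap(idx[col], idx[piv]);
    double p = A[idx[col]][col];
    if (std::fabs(p) < 1e-12) return false;
    for (int r = col + 1; r < 5; ++r) {
      double f = A[idx[r]][col] / p;
      for (int c = col; c < 5; ++c) A[idx[r]][c] -= f * A[idx[col]][c];
      b[idx[r]] -= f * b[idx[col]];
    }
  }
  for (int col = 4; col >= 0; --col) {
    double s = b[idx[col]];
    for (int c = col + 1; c < 5; ++c) s -= A[idx[col]][c] * x[c];
    x[col] = s / A[idx[col]][col];
  }
  return true;
}

// [[Rcpp::export(name = ".patch_curvature_cpp")]]
List patch_curvature_cpp(NumericMatrix V, NumericMatrix N, double rho) {
  const int n = V.nrow();
  NumericVector kmax(n), kmin(n);
  // uniform grid hash with cell size rho
  double mn[3];
  for (int k = 0; k < 3; ++k) {
    mn[k] = R_PosInf;
    for (int i = 0; i < n; ++i) if (V(i, k) < mn[k]) mn[k] = V(i, k);
  }
  auto cell_of = [&](double x, double y, double z) {
    long long cx = (long long)std::floor((x - mn[0]) / rho);
    long long cy = (long long)std::floor((y - mn[1]) / rho);
    long long cz = (long long)std::floor((z - mn[2]) / rho);
    return (cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL);
  };
  std::unordered_map<long long, std::vector<int> > grid;
  for (int i = 0; i < n; ++i)
    grid[cell_of(V(i, 0), V(i, 1), V(i, 2))].push_back(i);

  const double rho2 = rho * rho;
  for (int i = 0; i < n; ++i) {
    double nx = N(i, 0), ny = N(i, 1), nz = N(i, 2);
    // tangent frame
    double ax = 1, ay = 0, az = 0;
    if (std::fabs(nx) > 0.9) { ax = 0; ay = 1; }
    double dp = ax * nx + ay * ny + az * nz;
    double t1x = ax - dp * nx, t1y = ay - dp * ny, t1z = az - dp * nz;
    double tl = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
    t1x /= tl; t1y /= tl; t1z /= tl;
    double t2x = ny * t1z - nz * t1y;
    double t2y = nz * t1x - nx * t1z;
    double t2z = nx * t1y - ny * t1x;

    double AtA[5][5] = {{0}}, Atb[5] = {0};
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_of(V(i, 0) + dx * rho, V(i, 1) + dy * rho,
                                      V(i, 2) + dz * rho));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double px = V(j, 0) - V(i, 0);
            double py = V(j, 1) - V(i, 1);
            double pz = V(j, 2) - V(i, 2);
            if (px * px + py * py + pz * pz > rho2) continue;
            double u = px * t1x + py * t1y + pz * t1z;
            double w = px * t2x + py * t2y + pz * t2z;
            double h = px * nx + py * ny + pz * nz;
            double row[5] = {0.5 * u * u, u * w, 0.5 * w * w, u, w};
            for (int r = 0; r < 5; ++r) {
              for (int c = 0; c < 5; ++c) AtA[r][c] += row[r] * row[c];
              Atb[r] += row[r] * h;
            }
            ++cnt;
          }
        }
    double coef[5];
    double A[5][5], b[5];
    for (int r = 0; r < 5; ++r) { b[r] = Atb[r];
      for (int c = 0; c < 5; ++c) A[r][c] = AtA[r][c]; }
    if (cnt < 6 || !solve5(A, b, coef)) { kmax[i] = kmin[i] = 0; continue; }
    double a = -coef[0], bb = -coef[1], c = -coef[2];
    double tr = a + c;
    double disc = std::sqrt(std::max((a - c) * (a - c) + 4 * bb * bb, 0.0));
    kmax[i] = (tr + disc) / 2;
    kmin[i] = (tr - disc) / 2;
  }
  return List::create(_["k_max"] = kmax, _["k_min"] = kmin);
}
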