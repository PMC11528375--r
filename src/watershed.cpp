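#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 26-connected neighbourhood offsets for a grid of size (nx, ny, nz).
static inline void neighbors26(int x, int y, int z, int nx, int ny, int nz,
                               std::vector<R_xlen_t> &out) {
  out.clear();
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int dz = -1; dz <= 1; ++dz) {
    int zz = z + dz; if (zz < 0 || zz >= nz) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = y + dy; if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        if (dx == 0 && dy == 0 && dz == 0) continue;
        out.push_back((R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx);
      }
    }
  }
}

// Grayscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise), alternating raster sweeps until stable.
// [[Rcpp::export(name = ".grayrec_cpp")]]
NumericVector grayrec_cpp(NumericVector marker, NumericVector mask,
                          IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  std::vector<double> J(marker.begin(), marker.end());
  for (R_xlen_t i = 0; i < n; ++i) if (J[i] > mask[i]) J[i] = mask[i];

  bool changed = true;
  int guard = 0;
  std::vector<R_xlen_t> nb;
  while (changed && guard++ < 2000) {
    changed = false;
    // forward sweep
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
          double m = J[i];
          neighbors26(x, y, z, nx, ny, nz, nb);
          for (R_xlen_t j : nb) if (J[j] > m) m = J[j];
          if (m > mask[i]) m = mask[i];
          if (m > J[i]) { J[i] = m; changed = true; }
        }
    // backward sweep
    for (int z = nz - 1; z >= 0; --z)
      for (int y = ny - 1; y >= 0; --y)
        for (int x = nx - 1; x >= 0; --x) {
          R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
          double m = J[i];
          neighbors26(x, y, z, nx, ny, nz, nb);
          for (R_xlen_t j : nb) if (J[j] > m) m = J[j];
          if (m > mask[i]) m = mask[i];
          if (m > J[i]) { J[i] = m; changed = true; }
        }
  }
  return NumericVector(J.begin(), J.end());
}

// Label regional maxima (26-connected plateaus with no strictly greater
// neighbour) of `img` restricted to `support`. Returns integer labels,
// 0 = not a maximum.
// [[Rcpp::export(name = ".regmax_cpp")]]
IntegerVector regmax_cpp(NumericVector img, LogicalVector support,
                         IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n);            // 0 unvisited
  std::vector<signed char> state(n, 0); // 0 unknown, 1 in-plateau, 2 rejected
  std::vector<R_xlen_t> nb, plateau;
  int next = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!support[s] || state[s] != 0) continue;
    // flood the plateau of equal value containing s
    double v = img[s];
    bool is_max = true;
    plateau.clear();
    std::queue<R_xlen_t> q;
    q.push(s); state[s] = 1; plateau.push_back(s);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
      neighbors26(x, y, z, nx, ny, nz, nb);
      for (R_xlen_t j : nb) {
        if (!support[j]) continue;
        if (img[j] > v) { is_max = false; continue; }
        if (img[j] == v && state[j] == 0) {
          state[j] = 1; plateau.push_back(j); q.push(j);
        }
      }
    }
    int l = is_max ? ++next : 0;
    for (R_xlen_t i : plateau) { state[i] = 2; lab[i] = l; }
  }
  return lab;
}

// Marker-controlled watershed flood on `height` (flooding from high to low),
// restricted to `support`. `seeds` carries positive labels at marker voxels.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector height, IntegerVector seeds,
                            LogicalVector support, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n);
  struct Node { double h; R_xlen_t ord; R_xlen_t idx; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.h != b.h) return a.h < b.h;   // max-heap on height
      return a.ord > b.ord;               // FIFO among ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  R_xlen_t ord = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && support[i]) {
      lab[i] = seeds[i];
      pq.push({height[i], ord++, i});
    }
  std::vector<R_xlen_t> nb;
  while (!pq.empty()) {
    R_xlen_t i = pq.top().idx; pq.pop();
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
    neighbors26(x, y, z, nx, ny, nz, nb);
    for (R_xlen_t j : nb) {
      if (!support[j] || lab[j] != 0) continue;
      lab[j] = lab[i];
      pq.push({height[j], ord++, j});
    }
  }
  return lab;
}

// Plain 26-connected component labeling of a logical mask.
// [[Rcpp::export(name = ".cclabel_cpp")]]
IntegerVector cclabel_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n);
  std::vector<R_xlen_t> nb;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    std::queue<R_xlen_t> q;
    q.push(s); lab[s] = next;
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
      neighbors26(x, y, z, nx, ny, nz, nb);
      for (R_xlen_t j : nb)
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
    }
  }
  return lab;
}
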