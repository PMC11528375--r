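#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction at phi = 0 by marching tetrahedra on the Kuhn
// 6-tetrahedron decomposition of each grid cell. The Kuhn split uses the
// same main diagonal in every cell, so shared cell faces are triangulated
// identically and the welded mesh is watertight. Vertices are linearly
// interpolated along tetrahedron edges and reported in physical mm
// coordinates (voxel centre convention: origin + (i + 0.5) * spacing).

struct Key {
  R_xlen_t a, b;
  bool operator==(const Key &o) const { return a == o.a && b == o.b; }
};
struct KeyHash {
  size_t operator()(const Key &k) const {
    return std::hash<long long>()(((long long)k.a << 21) ^ (long long)k.b);
  }
};

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector phi, IntegerVector dim,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  // nudge exact zeros off the surface so no vertex coincides with a node
  std::vector<double> f(phi.begin(), phi.end());
  for (double &v : f) if (v == 0.0) v = 1e-12;

  // permutations defining the 6 Kuhn tetrahedra
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> tris;       // 0-based vertex ids

  auto node = [&](int x, int y, int z) -> R_xlen_t {
    return (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
  };
  auto edge_vertex = [&](R_xlen_t ia, R_xlen_t ib) -> int {
    Key k{std::min(ia, ib), std::max(ia, ib)};
    auto it = vmap.find(k);
    if (it != vmap.end()) return it->second;
    double fa = f[ia], fb = f[ib];
    double t = fa / (fa - fb);            // fa, fb have opposite signs
    if (t < 1e-9) t = 1e-9;
    if (t > 1.0 - 1e-9) t = 1.0 - 1e-9;
    int ax = (int)(ia % nx), ay = (int)((ia / nx) % ny), az = (int)(ia / nxy);
    int bx = (int)(ib % nx), by = (int)((ib / nx) % ny), bz = (int)(ib / nxy);
    double px = origin[0] + (ax + 0.5 + t * (bx - ax)) * spacing[0];
    double py = origin[1] + (ay + 0.5 + t * (by - ay)) * spacing[1];
    double pz = origin[2] + (az + 0.5 + t * (bz - az)) * spacing[2];
    int id = (int)(verts.size() / 3);
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    vmap.emplace(k, id);
    return id;
  };
  auto add_tri = [&](int v0, int v1, int v2,
                     const double *inC, const double *outC) {
    if (v0 == v1 || v1 == v2 || v0 == v2) return;
    const double *p0 = &verts[3 * v0], *p1 = &verts[3 * v1], *p2 = &verts[3 * v2];
    double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double nrm[3] = {u[1] * w[2] - u[2] * w[1],
                     u[2] * w[0] - u[0] * w[2],
                     u[0] * w[1] - u[1] * w[0]};
    double dir[3] = {outC[0] - inC[0], outC[1] - inC[1], outC[2] - inC[2]};
    double d = nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2];
    if (d >= 0) { tris.push_back(v0); tris.push_back(v1); tris.push_back(v2); }
    else        { tris.push_back(v0); tris.push_back(v2); tris.push_back(v1); }
  };

  R_xlen_t tv[4];
  double coord[4][3];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        // skip cells with uniform sign (cheap test on the 8 corners)
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          double v = f[node(x + (c & 1), y + ((c >> 1) & 1), z + (c >> 2))];
          if (v < 0) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          int d0[3] = {0, 0, 0}, d1[3] = {0, 0, 0}, d2[3] = {0, 0, 0};
          d1[perms[p][0]] = 1;
          d2[perms[p][0]] = 1; d2[perms[p][1]] = 1;
          int off[4][3] = {{0, 0, 0},
                           {d1[0], d1[1], d1[2]},
                           {d2[0], d2[1], d2[2]},
                           {1, 1, 1}};
          int nin = 0;
          int in_idx[4], out_idx[4];
          int nout = 0;
          for (int c = 0; c < 4; ++c) {
            tv[c] = node(x + off[c][0], y + off[c][1], z + off[c][2]);
            coord[c][0] = origin[0] + (x + off[c][0] + 0.5) * spacing[0];
            coord[c][1] = origin[1] + (y + off[c][1] + 0.5) * spacing[1];
            coord[c][2] = origin[2] + (z + off[c][2] + 0.5) * spacing[2];
            if (f[tv[c]] < 0) in_idx[nin++] = c; else out_idx[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          double inC[3] = {0, 0, 0}, outC[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int k = 0; k < 3; ++k) inC[k] += coord[in_idx[c]][k] / nin;
          for (int c = 0; c < nout; ++c)
            for (int k = 0; k < 3; ++k) outC[k] += coord[out_idx[c]][k] / nout;
          if (nin == 1) {
            int a = in_idx[0];
            int e0 = edge_vertex(tv[a], tv[out_idx[0]]);
            int e1 = edge_vertex(tv[a], tv[out_idx[1]]);
            int e2 = edge_vertex(tv[a], tv[out_idx[2]]);
            add_tri(e0, e1, e2, inC, outC);
          } else if (nin == 3) {
            int d = out_idx[0];
            int e0 = edge_vertex(tv[d], tv[in_idx[0]]);
            int e1 = edge_vertex(tv[d], tv[in_idx[1]]);
            int e2 = edge_vertex(tv[d], tv[in_idx[2]]);
            add_tri(e0, e1, e2, inC, outC);
          } else { // nin == 2
            int a = in_idx[0], b = in_idx[1];
            int c0 = out_idx[0], d0i = out_idx[1];
            int eac = edge_vertex(tv[a], tv[c0]);
            int ead = edge_vertex(tv[a], tv[d0i]);
            int ebd = edge_vertex(tv[b], tv[d0i]);
            int ebc = edge_vertex(tv[b], tv[c0]);
            add_tri(eac, ead, ebd, inC, outC);
            add_tri(eac, ebd, ebc, inC, outC);
          }
        }
      }

  const int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = verts[3 * i + k];
  for (int i = 0; i < nt; ++i)
    for (int k = 0; k < 3; ++k) T(i, k) = tris[3 * i + k] + 1; // 1-based
  return List::create(_["vertices"] = V, _["faces"] = T);
}
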