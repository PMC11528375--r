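#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact smallest enclosing ball in 3D: Welzl's recursive algorithm with
// move-to-front reordering. A brute-force enumeration over all candidate
// support subsets (sizes 2-4) is exported separately for use as an
// independent oracle at small n.

struct Ball { double c[3]; double r2; }; // r2 < 0 == empty

static inline double d2(const double *a, const double *b) {
  double s = 0; for (int k = 0; k < 3; ++k) { double d = a[k] - b[k]; s += d * d; }
  return s;
}
static inline bool contains(const Ball &B, const double *p) {
  if (B.r2 < 0) return false;
  return d2(B.c, p) <= B.r2 * (1.0 + 1e-10) + 1e-12;
}
static Ball ball0() { Ball b; b.c[0] = b.c[1] = b.c[2] = 0; b.r2 = -1; return b; }
static Ball ball1(const double *p) {
  Ball b; for (int k = 0; k < 3; ++k) b.c[k] = p[k]; b.r2 = 0; return b;
}
static Ball ball2(const double *p, const double *q) {
  Ball b;
  for (int k = 0; k < 3; ++k) b.c[k] = 0.5 * (p[k] + q[k]);
  b.r2 = d2(b.c, p);
  return b;
}
static inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static Ball ball3(const double *A, const double *Bp, const double *C) {
  double b[3], c[3], bxc[3];
  for (int k = 0; k < 3; ++k) { b[k] = Bp[k] - A[k]; c[k] = C[k] - A[k]; }
  cross3(b, c, bxc);
  double denom = 2.0 * (bxc[0] * bxc[0] + bxc[1] * bxc[1] + bxc[2] * bxc[2]);
  if (denom < 1e-24) return ball0(); // collinear
  double nb = b[0] * b[0] + b[1] * b[1] + b[2] * b[2];
  double nc = c[0] * c[0] + c[1] * c[1] + c[2] * c[2];
  double t1[3], t2[3];
  cross3(bxc, b, t1); // (b x c) x b
  cross3(c, bxc, t2); // c x (b x c)
  Ball o;
  for (int k = 0; k < 3; ++k)
    o.c[k] = A[k] + (nc * t1[k] + nb * t2[k]) / denom;
  o.r2 = d2(o.c, A);
  return o;
}
static Ball ball4(const double *p1, const double *p2, const double *p3,
                  const double *p4) {
  // solve 2 (pi - p1) . x = |pi|^2 - |p1|^2, i = 2..4 (Cramer)
  double M[3][3], rhs[3];
  const double *ps[3] = {p2, p3, p4};
  double n1 = p1[0]*p1[0] + p1[1]*p1[1] + p1[2]*p1[2];
  for (int i = 0; i < 3; ++i) {
    for (int k = 0; k < 3; ++k) M[i][k] = 2.0 * (ps[i][k] - p1[k]);
    double ni = ps[i][0]*ps[i][0] + ps[i][1]*ps[i][1] + ps[i][2]*ps[i][2];
    rhs[i] = ni - n1;
  }
  double det = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
             - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
             + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  if (std::fabs(det) < 1e-18) return ball0(); // coplanar
  auto solve_col = [&](int col) {
    double T[3][3];
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) T[i][k] = (k == col) ? rhs[i] : M[i][k];
    return (T[0][0]*(T[1][1]*T[2][2]-T[1][2]*T[2][1])
          - T[0][1]*(T[1][0]*T[2][2]-T[1][2]*T[2][0])
          + T[0][2]*(T[1][0]*T[2][1]-T[1][1]*T[2][0])) / det;
  };
  Ball o;
  for (int k = 0; k < 3; ++k) o.c[k] = solve_col(k);
  o.r2 = d2(o.c, p1);
  return o;
}
static Ball ball_of(const double *B[4], int nb) {
  switch (nb) {
    case 0: return ball0();
    case 1: return ball1(B[0]);
    case 2: return ball2(B[0], B[1]);
    case 3: return ball3(B[0], B[1], B[2]);
    default: return ball4(B[0], B[1], B[2], B[3]);
  }
}

static std::vector<const double *> g_pts;
static const double *g_B[4];

static Ball welzl_mtf(int n, int nb) {
  Ball b = ball_of(g_B, nb);
  if (nb == 4) return b;
  for (int i = 0; i < n; ++i) {
    const double *p = g_pts[i];
    if (!contains(b, p)) {
      g_B[nb] = p;
      b = welzl_mtf(i, nb + 1);
      // move to front
      for (int j = i; j > 0; --j) g_pts[j] = g_pts[j - 1];
      g_pts[0] = p;
    }
  }
  return b;
}

// [[Rcpp::export(name = ".miniball_cpp")]]
List miniball_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<double> buf(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) buf[3 * i + k] = pts(i, k);
  g_pts.resize(n);
  for (int i = 0; i < n; ++i) g_pts[i] = &buf[3 * i];
  Ball b = (n == 0) ? ball0() : welzl_mtf(n, 0);
  g_pts.clear();
  return List::create(_["center"] = NumericVector::create(b.c[0], b.c[1], b.c[2]),
                      _["radius"] = b.r2 < 0 ? NA_REAL : std::sqrt(b.r2));
}

// [[Rcpp::export(name = ".bruteball_cpp")]]
List bruteball_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<double> buf(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) buf[3 * i + k] = pts(i, k);
  auto P = [&](int i) { return &buf[3 * i]; };
  Ball best = ball0();
  double bestr2 = R_PosInf;
  auto consider = [&](Ball b) {
    if (b.r2 < 0 || b.r2 >= bestr2) return;
    for (int i = 0; i < n; ++i) if (!contains(b, P(i))) return;
    best = b; bestr2 = b.r2;
  };
  if (n == 1) consider(ball1(P(0)));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      consider(ball2(P(i), P(j)));
      for (int k = j + 1; k < n; ++k) {
        consider(ball3(P(i), P(j), P(k)));
        for (int l = k + 1; l < n; ++l)
          consider(ball4(P(i), P(j), P(k), P(l)));
      }
    }
  return List::create(_["center"] = NumericVector::create(best.c[0], best.c[1], best.c[2]),
                      _["radius"] = best.r2 < 0 ? NA_REAL : std::sqrt(best.r2));
}
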