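#include <Rcpp.h>
#include <array>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay tetrahedralization in 3D.
//
// Double-precision insphere tests via cached circumcenters; geometric
// inconsistencies (empty cavity, non-manifold cavity boundary, degenerate
// new simplex) abort with a "delaunay_retry" error so the R wrapper can
// re-run on deterministically jittered coordinates.

struct Tet {
  int v[4];
  double c[3];  // circumcenter
  double r2;    // squared circumradius
  bool alive;
};

typedef std::vector<std::array<double, 3> > Pts;

static double dist2(const double *a, const double *b) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) {
    double d = a[j] - b[j];
    s += d * d;
  }
  return s;
}

// circumcenter of the tetrahedron; false when (near-)degenerate
static bool circumsphere(const Pts &P, const int v[4], double c[3],
                         double &r2) {
  const double *A = P[v[0]].data();
  double M[3][3], b[3], scale = 1.0;
  for (int i = 0; i < 3; ++i) {
    const double *Q = P[v[i + 1]].data();
    double nb = 0.0, len2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      double d = Q[j] - A[j];
      M[i][j] = d;
      nb += d * (Q[j] + A[j]);
      len2 += d * d;
    }
    b[i] = 0.5 * nb;
    scale *= std::sqrt(len2);  // product of edge lengths from A
  }
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  // scale-invariant degeneracy measure (product of the sines of the
  // spanning angles); exact coplanarity gives det = 0
  if (std::fabs(det) < 1e-12 * scale) return false;
  double x = b[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
             M[0][1] * (b[1] * M[2][2] - M[1][2] * b[2]) +
             M[0][2] * (b[1] * M[2][1] - M[1][1] * b[2]);
  double y = M[0][0] * (b[1] * M[2][2] - M[1][2] * b[2]) -
             b[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
             M[0][2] * (M[1][0] * b[2] - b[1] * M[2][0]);
  double z = M[0][0] * (M[1][1] * b[2] - b[1] * M[2][1]) -
             M[0][1] * (M[1][0] * b[2] - b[1] * M[2][0]) +
             b[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  c[0] = x / det;
  c[1] = y / det;
  c[2] = z / det;
  r2 = dist2(c, A);
  return true;
}

static void push_tet(std::vector<Tet> &T, const Pts &P, int a, int b, int c,
                     int d) {
  Tet t;
  t.v[0] = a;
  t.v[1] = b;
  t.v[2] = c;
  t.v[3] = d;
  t.alive = true;
  if (!circumsphere(P, t.v, t.c, t.r2))
    stop("delaunay_retry: degenerate simplex encountered");
  T.push_back(t);
}

// [[Rcpp::export]]
IntegerMatrix delaunay3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  Pts P((size_t)n + 4);
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) {
    lo[j] = R_PosInf;
    hi[j] = R_NegInf;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      P[i][j] = v;
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  }
  double ctr[3], span = 0.0;
  for (int j = 0; j < 3; ++j) {
    ctr[j] = 0.5 * (lo[j] + hi[j]);
    if (hi[j] - lo[j] > span) span = hi[j] - lo[j];
  }
  // super-tetrahedron far outside every circumsphere of the true simplices
  double R = 1e3 * (span + 1.0);
  const double sv[4][3] = {{0.0, 0.0, 3.0},
                           {2.82842712474619, 0.0, -1.0},
                           {-1.41421356237310, 2.44948974968164, -1.0},
                           {-1.41421356237310, -2.44948974968164, -1.0}};
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j) P[n + k][j] = ctr[j] + R * sv[k][j];

  std::vector<Tet> T;
  push_tet(T, P, n, n + 1, n + 2, n + 3);

  std::vector<size_t> bad;
  typedef std::array<int, 3> Face;
  std::map<Face, int> fcount;

  for (int i = 0; i < n; ++i) {
    const double *p = P[i].data();
    bad.clear();
    for (size_t t = 0; t < T.size(); ++t) {
      if (!T[t].alive) continue;
      if (dist2(p, T[t].c) < T[t].r2) bad.push_back(t);
    }
    if (bad.empty())
      stop("delaunay_retry: point %d outside every circumsphere", i + 1);

    fcount.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      const int *v = T[bad[k]].v;
      for (int drop = 0; drop < 4; ++drop) {
        Face f;
        int m = 0;
        for (int j = 0; j < 4; ++j)
          if (j != drop) f[m++] = v[j];
        std::sort(f.begin(), f.end());
        ++fcount[f];
      }
      T[bad[k]].alive = false;
    }
    for (std::map<Face, int>::const_iterator it = fcount.begin();
         it != fcount.end(); ++it) {
      if (it->second > 2)
        stop("delaunay_retry: non-manifold cavity at point %d", i + 1);
      if (it->second == 1)
        push_tet(T, P, it->first[0], it->first[1], it->first[2], i);
    }
    if (i % 64 == 0) checkUserInterrupt();
  }

  std::vector<const Tet *> keep;
  for (size_t t = 0; t < T.size(); ++t) {
    if (!T[t].alive) continue;
    bool real = true;
    for (int j = 0; j < 4; ++j)
      if (T[t].v[j] >= n) real = false;
    if (real) keep.push_back(&T[t]);
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (size_t t = 0; t < keep.size(); ++t) {
    std::array<int, 4> v;
    for (int j = 0; j < 4; ++j) v[j] = keep[t]->v[j];
    std::sort(v.begin(), v.end());
    for (int j = 0; j < 4; ++j) out((int)t, j) = v[j] + 1;  // 1-based
  }
  return out;
}
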