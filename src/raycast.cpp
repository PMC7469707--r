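#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nearest positive ray/mesh intersection (Moller-Trumbore, back faces accepted).
//
// origins, dirs : n_rays x 3
// V             : n_vertices x 3
// F             : n_faces x 3, 1-based vertex indices
// eps           : parallel-ray determinant cutoff
//
// Returns list(t = distance to nearest hit or NA, tri = 1-based face id or NA).
// A small barycentric slack keeps rays that graze shared edges from slipping
// between adjacent triangles.
// [[Rcpp::export]]
List ray_mesh_nearest(NumericMatrix origins, NumericMatrix dirs,
                      NumericMatrix V, IntegerMatrix F,
                      double eps = 1e-12) {
  const int nr = origins.nrow();
  const int nf = F.nrow();
  const double bslack = 1e-9;

  std::vector<double> v0(3 * nf), e1(3 * nf), e2(3 * nf);
  for (int i = 0; i < nf; ++i) {
    const int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      v0[3 * i + k] = V(a, k);
      e1[3 * i + k] = V(b, k) - V(a, k);
      e2[3 * i + k] = V(c, k) - V(a, k);
    }
  }

  NumericVector tmin(nr, NA_REAL);
  IntegerVector hit(nr, NA_INTEGER);

  for (int r = 0; r < nr; ++r) {
    const double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    const double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = R_PosInf;
    int best_i = NA_INTEGER;
    for (int i = 0; i < nf; ++i) {
      const double *a = &v0[3 * i], *p = &e1[3 * i], *q = &e2[3 * i];
      // pvec = d x e2
      const double px = dy * q[2] - dz * q[1];
      const double py = dz * q[0] - dx * q[2];
      const double pz = dx * q[1] - dy * q[0];
      const double det = p[0] * px + p[1] * py + p[2] * pz;
      if (std::fabs(det) < eps) continue;
      const double inv = 1.0 / det;
      const double tx = ox - a[0], ty = oy - a[1], tz = oz - a[2];
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -bslack || u > 1.0 + bslack) continue;
      // qvec = tvec x e1
      const double qx = ty * p[2] - tz * p[1];
      const double qy = tz * p[0] - tx * p[2];
      const double qz = tx * p[1] - ty * p[0];
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -bslack || u + v > 1.0 + bslack) continue;
      const double t = (q[0] * qx + q[1] * qy + q[2] * qz) * inv;
      if (t > eps && t < best) {
        best = t;
        best_i = i + 1;
      }
    }
    if (best_i != NA_INTEGER) {
      tmin[r] = best;
      hit[r] = best_i;
    }
  }
  return List::create(_["t"] = tmin, _["tri"] = hit);
}
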