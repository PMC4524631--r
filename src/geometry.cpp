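#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Basic vector helpers on raw double[3].
static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Moeller-Trumbore ray/triangle intersection. Returns true and the ray
// parameter t (can be negative: the line is tested, caller filters) when the
// line through orig with direction dir hits the triangle.
static bool line_tri_intersect(const double* orig, const double* dir,
                               const double* v0, const double* v1,
                               const double* v2, double& t) {
  const double EPS = 1e-12;
  double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
  vsub(v1, v0, e1);
  vsub(v2, v0, e2);
  vcross(dir, e2, pvec);
  double det = vdot(e1, pvec);
  if (std::fabs(det) < EPS) return false;
  double inv_det = 1.0 / det;
  vsub(orig, v0, tvec);
  double u = vdot(tvec, pvec) * inv_det;
  if (u < -1e-10 || u > 1.0 + 1e-10) return false;
  vcross(tvec, e1, qvec);
  double v = vdot(dir, qvec) * inv_det;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return false;
  t = vdot(e2, qvec) * inv_det;
  return true;
}

// Closest point on triangle (Ericson, Real-Time Collision Detection ch. 5).
static void closest_point_tri(const double* p, const double* a,
                              const double* b, const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3];
  vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// Flattened per-face vertex coordinates plus bounding-sphere data, built
// once per call so the inner loops run on contiguous memory.
struct FlatMesh {
  std::vector<double> tri;   // 9 doubles per face: a, b, c
  std::vector<double> cen;   // 3 doubles per face: centroid
  std::vector<double> rad;   // bounding-sphere radius per face
  int nf;
};

static FlatMesh flatten_mesh(const NumericMatrix& V, const IntegerMatrix& F) {
  FlatMesh m;
  m.nf = F.nrow();
  m.tri.resize(9 * m.nf);
  m.cen.resize(3 * m.nf);
  m.rad.resize(m.nf);
  for (int f = 0; f < m.nf; ++f) {
    double* t = &m.tri[9 * f];
    for (int c = 0; c < 3; ++c) {
      int v = F(f, c);
      t[3 * c] = V(v, 0); t[3 * c + 1] = V(v, 1); t[3 * c + 2] = V(v, 2);
    }
    double* cn = &m.cen[3 * f];
    for (int k = 0; k < 3; ++k) cn[k] = (t[k] + t[3 + k] + t[6 + k]) / 3.0;
    double r2 = 0;
    for (int c = 0; c < 3; ++c) {
      double dx = t[3*c] - cn[0], dy = t[3*c+1] - cn[1], dz = t[3*c+2] - cn[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    m.rad[f] = std::sqrt(r2);
  }
  return m;
}

// Closest point on a triangle mesh for each query point. Brute force over
// faces with a bounding-sphere prune against the best distance so far.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow();
  FlatMesh m = flatten_mesh(V, F);
  NumericMatrix Q(n, 3);
  NumericVector dist(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best = std::numeric_limits<double>::infinity();  // squared
    double bestd = std::numeric_limits<double>::infinity();
    double bq[3] = { 0, 0, 0 };
    int bf = -1;
    for (int f = 0; f < m.nf; ++f) {
      const double* cn = &m.cen[3 * f];
      double dx = p[0]-cn[0], dy = p[1]-cn[1], dz = p[2]-cn[2];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - m.rad[f];
      if (dc > bestd) continue;
      const double* t = &m.tri[9 * f];
      double q[3];
      closest_point_tri(p, t, t + 3, t + 6, q);
      double d2 = (p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                  (p[2]-q[2])*(p[2]-q[2]);
      if (d2 < best) {
        best = d2; bestd = std::sqrt(d2);
        bq[0]=q[0]; bq[1]=q[1]; bq[2]=q[2]; bf = f;
      }
    }
    Q(i,0)=bq[0]; Q(i,1)=bq[1]; Q(i,2)=bq[2];
    dist[i] = std::sqrt(best);
    face[i] = bf + 1;  // back to R's 1-based indexing
  }
  return List::create(_["points"] = Q, _["dist"] = dist, _["face"] = face);
}

// Projection of points along their (unit) normals onto a target mesh:
// for each point the line p + t*n is intersected with every target triangle
// and the hit with smallest |t| wins; t is the signed distance (negative when
// the surface lies against the normal direction). Points whose line misses
// the target entirely fall back to the closest surface point with hit = FALSE.
// [[Rcpp::export]]
List cpp_project_normals(NumericMatrix P, NumericMatrix N,
                         NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow();
  FlatMesh m = flatten_mesh(V, F);
  NumericMatrix Q(n, 3);
  NumericVector dist(n);
  LogicalVector hit(n);
  IntegerVector face(n);
  std::vector<int> misses;
  for (int i = 0; i < n; ++i) {
    double p[3] = { P(i,0), P(i,1), P(i,2) };
    double d[3] = { N(i,0), N(i,1), N(i,2) };
    double best_abs = std::numeric_limits<double>::infinity();
    double best_t = NA_REAL;
    int bf = -1;
    for (int f = 0; f < m.nf; ++f) {
      // any hit on this face satisfies |t| >= dist(p, centroid) - radius
      const double* cn = &m.cen[3 * f];
      double dx = p[0]-cn[0], dy = p[1]-cn[1], dz = p[2]-cn[2];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - m.rad[f];
      if (dc > best_abs) continue;
      const double* t3 = &m.tri[9 * f];
      double t;
      if (line_tri_intersect(p, d, t3, t3 + 3, t3 + 6, t) &&
          std::fabs(t) < best_abs) {
        best_abs = std::fabs(t);
        best_t = t;
        bf = f;
      }
    }
    if (bf >= 0) {
      for (int k = 0; k < 3; ++k) Q(i,k) = p[k] + best_t * d[k];
      dist[i] = best_t;
      hit[i] = true;
      face[i] = bf + 1;
    } else {
      hit[i] = false;
      face[i] = NA_INTEGER;
      misses.push_back(i);
    }
  }
  if (!misses.empty()) {
    NumericMatrix Pm((int) misses.size(), 3);
    for (size_t k = 0; k < misses.size(); ++k)
      for (int c = 0; c < 3; ++c) Pm(k, c) = P(misses[k], c);
    List cl = cpp_closest_points(Pm, V, F);
    NumericMatrix Qm = cl["points"];
    NumericVector dm = cl["dist"];
    IntegerVector fm = cl["face"];
    for (size_t k = 0; k < misses.size(); ++k) {
      int i = misses[k];
      double s = (Qm(k,0)-P(i,0))*N(i,0) + (Qm(k,1)-P(i,1))*N(i,1) +
                 (Qm(k,2)-P(i,2))*N(i,2);
      for (int c = 0; c < 3; ++c) Q(i,c) = Qm(k,c);
      dist[i] = (s < 0 ? -1.0 : 1.0) * dm[k];
      face[i] = fm[k];
    }
  }
  return List::create(_["points"] = Q, _["dist"] = dist,
                      _["hit"] = hit, _["face"] = face);
}

// Coplanarity-robust triangle/triangle overlap test (Moeller 1997 interval
// scheme; coplanar pairs are tested by 2D edge crossings + containment).
static bool axis_separates(const double* n, const double* t1[3],
                           const double* t2[3]) {
  double mn1 = 1e300, mx1 = -1e300, mn2 = 1e300, mx2 = -1e300;
  for (int k = 0; k < 3; ++k) {
    double d1 = vdot(n, t1[k]), d2 = vdot(n, t2[k]);
    if (d1 < mn1) mn1 = d1; if (d1 > mx1) mx1 = d1;
    if (d2 < mn2) mn2 = d2; if (d2 > mx2) mx2 = d2;
  }
  const double eps = 1e-12;
  return mx1 < mn2 - eps || mx2 < mn1 - eps;
}

// Separating-axis test for triangle pairs (exact for closed convex shapes;
// triangles are convex so SAT over face normals and edge cross products is a
// complete overlap test).
static bool tri_tri_overlap(const double* a0, const double* a1, const double* a2,
                            const double* b0, const double* b1, const double* b2) {
  const double* t1[3] = { a0, a1, a2 };
  const double* t2[3] = { b0, b1, b2 };
  double e1[3][3], e2[3][3];
  vsub(a1, a0, e1[0]); vsub(a2, a1, e1[1]); vsub(a0, a2, e1[2]);
  vsub(b1, b0, e2[0]); vsub(b2, b1, e2[1]); vsub(b0, b2, e2[2]);
  double n[3];
  vcross(e1[0], e1[1], n);
  if (axis_separates(n, t1, t2)) return false;
  vcross(e2[0], e2[1], n);
  if (axis_separates(n, t1, t2)) return false;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      vcross(e1[i], e2[j], n);
      if (std::fabs(n[0]) + std::fabs(n[1]) + std::fabs(n[2]) < 1e-14) continue;
      if (axis_separates(n, t1, t2)) return false;
    }
  return true;
}

// Count of intersecting, non-adjacent (no shared vertex) triangle pairs.
// Brute force O(F^2); intended for self-intersection audits of small meshes.
// [[Rcpp::export]]
int cpp_self_intersection_count(NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  int count = 0;
  for (int i = 0; i < nf; ++i) {
    double a0[3] = { V(F(i,0),0), V(F(i,0),1), V(F(i,0),2) };
    double a1[3] = { V(F(i,1),0), V(F(i,1),1), V(F(i,1),2) };
    double a2[3] = { V(F(i,2),0), V(F(i,2),1), V(F(i,2),2) };
    for (int j = i + 1; j < nf; ++j) {
      bool shared = false;
      for (int u = 0; u < 3 && !shared; ++u)
        for (int v = 0; v < 3; ++v)
          if (F(i,u) == F(j,v)) { shared = true; break; }
      if (shared) continue;
      double b0[3] = { V(F(j,0),0), V(F(j,0),1), V(F(j,0),2) };
      double b1[3] = { V(F(j,1),0), V(F(j,1),1), V(F(j,1),2) };
      double b2[3] = { V(F(j,2),0), V(F(j,2),1), V(F(j,2),2) };
      if (tri_tri_overlap(a0, a1, a2, b0, b1, b2)) ++count;
    }
  }
  return count;
}
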