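// Ray casting (BVH-accelerated + brute force) and point-to-triangle
// closest distance for indexed triangle meshes.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

struct Tri { Vec3 a, b, c; int id; };

struct AABB {
  Vec3 lo, hi;
  AABB() {
    double inf = std::numeric_limits<double>::infinity();
    lo = Vec3(inf, inf, inf); hi = Vec3(-inf, -inf, -inf);
  }
  void grow(const Vec3& p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
  void grow(const Tri& t) { grow(t.a); grow(t.b); grow(t.c); }
  // slab test; returns entry t or inf if missed (ray: o + t*d, t >= 0)
  double ray_enter(const Vec3& o, const Vec3& inv_d, double tmax) const {
    double t0 = 0.0, t1 = tmax;
    const double* lo_p = &lo.x; const double* hi_p = &hi.x;
    const double* o_p = &o.x;   const double* id_p = &inv_d.x;
    for (int k = 0; k < 3; ++k) {
      double ta = (lo_p[k] - o_p[k]) * id_p[k];
      double tb = (hi_p[k] - o_p[k]) * id_p[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      if (t0 > t1) return std::numeric_limits<double>::infinity();
    }
    return t0;
  }
  double dist2_point(const Vec3& p) const {
    double d2 = 0.0;
    const double* lo_p = &lo.x; const double* hi_p = &hi.x; const double* pp = &p.x;
    for (int k = 0; k < 3; ++k) {
      double d = 0.0;
      if (pp[k] < lo_p[k]) d = lo_p[k] - pp[k];
      else if (pp[k] > hi_p[k]) d = pp[k] - hi_p[k];
      d2 += d * d;
    }
    return d2;
  }
};

// Moller-Trumbore; returns t (> 0) or -1 on miss. Small slack on the
// barycentric bounds so shared edges do not leak rays.
static inline double ray_tri(const Vec3& o, const Vec3& d, const Tri& tr,
                             double& u_out, double& v_out) {
  const double EPS = 1e-12, BEPS = 1e-9;
  Vec3 e1 = tr.b - tr.a, e2 = tr.c - tr.a;
  Vec3 pv = d.cross(e2);
  double det = e1.dot(pv);
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  Vec3 tv = o - tr.a;
  double u = tv.dot(pv) * inv;
  if (u < -BEPS || u > 1.0 + BEPS) return -1.0;
  Vec3 qv = tv.cross(e1);
  double v = d.dot(qv) * inv;
  if (v < -BEPS || u + v > 1.0 + BEPS) return -1.0;
  double t = e2.dot(qv) * inv;
  if (t <= 0.0) return -1.0;
  u_out = u; v_out = v;
  return t;
}

// Closest point on triangle to p (Ericson, Real-Time Collision Detection).
static Vec3 closest_on_tri(const Vec3& p, const Tri& t) {
  Vec3 ab = t.b - t.a, ac = t.c - t.a, ap = p - t.a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0.0 && d2 <= 0.0) return t.a;
  Vec3 bp = p - t.b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0.0 && d4 <= d3) return t.b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return t.a + ab * v;
  }
  Vec3 cp = p - t.c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0.0 && d5 <= d6) return t.c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return t.a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return t.b + (t.c - t.b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return t.a + ab * v + ac * w;
}

struct BVHNode {
  AABB box;
  int left = -1, right = -1; // children, or leaf range below
  int first = 0, count = 0;  // leaf triangle range
  bool leaf() const { return count > 0; }
};

struct BVH {
  std::vector<Tri> tris;          // permuted into leaf order
  std::vector<BVHNode> nodes;

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    tris.resize(m);
    for (int i = 0; i < m; ++i) {
      int a = F(i, 0), b = F(i, 1), c = F(i, 2);
      tris[i].a = Vec3(V(a, 0), V(a, 1), V(a, 2));
      tris[i].b = Vec3(V(b, 0), V(b, 1), V(b, 2));
      tris[i].c = Vec3(V(c, 0), V(c, 1), V(c, 2));
      tris[i].id = i;
    }
    nodes.clear();
    nodes.reserve(2 * m);
    build_node(0, m);
  }

  int build_node(int first, int count) {
    int idx = (int)nodes.size();
    nodes.push_back(BVHNode());
    AABB box;
    for (int i = first; i < first + count; ++i) box.grow(tris[i]);
    nodes[idx].box = box;
    if (count <= 4) {
      nodes[idx].first = first; nodes[idx].count = count;
      return idx;
    }
    // split at median centroid along the longest axis
    Vec3 ext = box.hi - box.lo;
    int axis = 0;
    if (ext.y > ext.x) axis = 1;
    if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
    int mid = first + count / 2;
    std::nth_element(tris.begin() + first, tris.begin() + mid,
                     tris.begin() + first + count,
                     [axis](const Tri& p, const Tri& q) {
                       auto cen = [axis](const Tri& t) {
                         const double* a = &t.a.x; const double* b = &t.b.x;
                         const double* c = &t.c.x;
                         return a[axis] + b[axis] + c[axis];
                       };
                       return cen(p) < cen(q);
                     });
    int l = build_node(first, mid - first);
    int r = build_node(mid, first + count - mid);
    nodes[idx].left = l; nodes[idx].right = r;
    return idx;
  }

  // nearest hit with t > tmin
  bool raycast(const Vec3& o, const Vec3& d, double tmin,
               double& t_out, int& face_out) const {
    Vec3 inv_d(1.0 / d.x, 1.0 / d.y, 1.0 / d.z);
    double best = std::numeric_limits<double>::infinity();
    int best_face = -1;
    int stack[128]; int sp = 0;
    stack[sp++] = 0;
    while (sp > 0) {
      const BVHNode& nd = nodes[stack[--sp]];
      if (nd.box.ray_enter(o, inv_d, best) == std::numeric_limits<double>::infinity())
        continue;
      if (nd.leaf()) {
        for (int i = nd.first; i < nd.first + nd.count; ++i) {
          double u, v;
          double t = ray_tri(o, d, tris[i], u, v);
          if (t > tmin && t < best) { best = t; best_face = tris[i].id; }
        }
      } else {
        stack[sp++] = nd.left;
        stack[sp++] = nd.right;
      }
    }
    t_out = best; face_out = best_face;
    return best_face >= 0;
  }

  void closest(const Vec3& p, double& dist_out, Vec3& q_out, int& face_out) const {
    double best2 = std::numeric_limits<double>::infinity();
    Vec3 best_q; int best_face = -1;
    // prioritized DFS: visit nearer child first
    struct Item { int node; double d2; };
    Item stack[128]; int sp = 0;
    stack[sp++] = { 0, nodes[0].box.dist2_point(p) };
    while (sp > 0) {
      Item it = stack[--sp];
      if (it.d2 >= best2) continue;
      const BVHNode& nd = nodes[it.node];
      if (nd.leaf()) {
        for (int i = nd.first; i < nd.first + nd.count; ++i) {
          Vec3 q = closest_on_tri(p, tris[i]);
          double d2 = (p - q).dot(p - q);
          if (d2 < best2) { best2 = d2; best_q = q; best_face = tris[i].id; }
        }
      } else {
        double dl = nodes[nd.left].box.dist2_point(p);
        double dr = nodes[nd.right].box.dist2_point(p);
        // push farther first so nearer is processed first
        if (dl < dr) {
          if (dr < best2) stack[sp++] = { nd.right, dr };
          if (dl < best2) stack[sp++] = { nd.left, dl };
        } else {
          if (dl < best2) stack[sp++] = { nd.left, dl };
          if (dr < best2) stack[sp++] = { nd.right, dr };
        }
      }
    }
    dist_out = std::sqrt(best2); q_out = best_q; face_out = best_face;
  }
};

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<BVH> ptr(new BVH(), true);
  ptr->build(V, F);
  return ptr;
}

// [[Rcpp::export]]
List cpp_raycast(SEXP bvh_ptr, NumericMatrix origins, NumericMatrix dirs,
                 double ignore_within) {
  XPtr<BVH> bvh(bvh_ptr);
  int n = origins.nrow();
  LogicalVector hit(n);
  NumericVector dist(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    double t; int f;
    if (bvh->raycast(o, d, ignore_within, t, f)) {
      hit[i] = true; dist[i] = t; face[i] = f + 1;
    } else {
      hit[i] = false; dist[i] = NA_REAL; face[i] = NA_INTEGER;
    }
  }
  return List::create(_["hit"] = hit, _["distance"] = dist, _["face"] = face);
}

// [[Rcpp::export]]
List cpp_raycast_brute(NumericMatrix V, IntegerMatrix F, NumericMatrix origins,
                       NumericMatrix dirs, double ignore_within) {
  int m = F.nrow(), n = origins.nrow();
  std::vector<Tri> tris(m);
  for (int i = 0; i < m; ++i) {
    int a = F(i, 0), b = F(i, 1), c = F(i, 2);
    tris[i].a = Vec3(V(a, 0), V(a, 1), V(a, 2));
    tris[i].b = Vec3(V(b, 0), V(b, 1), V(b, 2));
    tris[i].c = Vec3(V(c, 0), V(c, 1), V(c, 2));
    tris[i].id = i;
  }
  LogicalVector hit(n);
  NumericVector dist(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    double best = std::numeric_limits<double>::infinity();
    int best_face = -1;
    for (int j = 0; j < m; ++j) {
      double u, v;
      double t = ray_tri(o, d, tris[j], u, v);
      if (t > ignore_within && t < best) { best = t; best_face = j; }
    }
    if (best_face >= 0) { hit[i] = true; dist[i] = best; face[i] = best_face + 1; }
    else { hit[i] = false; dist[i] = NA_REAL; face[i] = NA_INTEGER; }
  }
  return List::create(_["hit"] = hit, _["distance"] = dist, _["face"] = face);
}

// [[Rcpp::export]]
List cpp_closest(SEXP bvh_ptr, NumericMatrix points) {
  XPtr<BVH> bvh(bvh_ptr);
  int n = points.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    double d; Vec3 q; int f;
    bvh->closest(p, d, q, f);
    dist[i] = d;
    closest(i, 0) = q.x; closest(i, 1) = q.y; closest(i, 2) = q.z;
    face[i] = f + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = closest, _["face"] = face);
}

// [[Rcpp::export]]
NumericVector cpp_closest_brute(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix points) {
  int m = F.nrow(), n = points.nrow();
  std::vector<Tri> tris(m);
  for (int i = 0; i < m; ++i) {
    int a = F(i, 0), b = F(i, 1), c = F(i, 2);
    tris[i].a = Vec3(V(a, 0), V(a, 1), V(a, 2));
    tris[i].b = Vec3(V(b, 0), V(b, 1), V(b, 2));
    tris[i].c = Vec3(V(c, 0), V(c, 1), V(c, 2));
  }
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    double best2 = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      Vec3 q = closest_on_tri(p, tris[j]);
      double d2 = (p - q).dot(p - q);
      if (d2 < best2) best2 = d2;
    }
    dist[i] = std::sqrt(best2);
  }
  return dist;
}
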