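// Geometry kernels: ray/triangle intersection (Moller-Trumbore), software
// rasterization through the pinhole model, point-to-surface closest points,
// ray-to-surface nearest points and vertex normals. All routines are exact
// exhaustive loops over triangles; meshes in this package are small enough
// (<100k triangles) that no acceleration structure is needed.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline void vsub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// Moller-Trumbore without backface culling. Hit requires t > 1e-9 so the
// reported distance is strictly positive. Barycentrics: u weights vertex b,
// v weights vertex c.
static inline bool mt_hit(const double* o, const double* d,
                          const double* a, const double* b, const double* c,
                          double& t, double& u, double& v) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  vsub(b, a, e1);
  vsub(c, a, e2);
  vcross(d, e2, pv);
  double det = vdot(e1, pv);
  if (std::fabs(det) < 1e-12) return false;
  double inv = 1.0 / det;
  vsub(o, a, tv);
  u = vdot(tv, pv) * inv;
  if (u < 0.0 || u > 1.0) return false;
  vcross(tv, e1, qv);
  v = vdot(d, qv) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  t = vdot(e2, qv) * inv;
  return t > 1e-9;
}

static inline void get_vertex(const NumericMatrix& V, int i, double* out) {
  out[0] = V(i, 0); out[1] = V(i, 1); out[2] = V(i, 2);
}

// [[Rcpp::export]]
List cpp_cast_rays(const NumericMatrix& V, const IntegerMatrix& F,
                   const NumericMatrix& origins, const NumericMatrix& dirs) {
  const int nr = origins.nrow(), nf = F.nrow();
  IntegerVector tri(nr, NA_INTEGER);
  NumericVector dist(nr, NA_REAL);
  NumericMatrix point(nr, 3);
  NumericMatrix bary(nr, 2);
  std::fill(point.begin(), point.end(), NA_REAL);
  for (int r = 0; r < nr; ++r) {
    double o[3] = { origins(r, 0), origins(r, 1), origins(r, 2) };
    double d[3] = { dirs(r, 0), dirs(r, 1), dirs(r, 2) };
    double best_t = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_u = 0, best_v = 0;
    for (int f = 0; f < nf; ++f) {
      double a[3], b[3], c[3], t, u, v;
      get_vertex(V, F(f, 0), a);
      get_vertex(V, F(f, 1), b);
      get_vertex(V, F(f, 2), c);
      if (mt_hit(o, d, a, b, c, t, u, v) && t < best_t) {
        best_t = t; best_f = f; best_u = u; best_v = v;
      }
    }
    if (best_f >= 0) {
      tri[r] = best_f + 1;  // 1-based for R
      dist[r] = best_t;
      for (int k = 0; k < 3; ++k) point(r, k) = o[k] + best_t * d[k];
      bary(r, 0) = best_u; bary(r, 1) = best_v;
    }
  }
  return List::create(_["triangle"] = tri, _["distance"] = dist,
                      _["point"] = point, _["bary"] = bary);
}

// Unlit z-buffered rasterizer. Pixel (ix, iy), 0-based, has its center at
// image coordinates (ix + 0.5, iy + 0.5); origin top-left, x right, y down.
// Each covered pixel's depth is the distance from the camera position to the
// surface along that pixel's (unit) ray, so rendering agrees exactly with
// cast_ray along pixel rays. Triangles with any vertex not strictly in front
// of the camera are skipped (no near-plane clipping; scan subjects are far
// from the camera).
// [[Rcpp::export]]
List cpp_render(const NumericMatrix& V, const IntegerMatrix& F,
                const NumericMatrix& C,
                const NumericVector& pos, const NumericVector& right,
                const NumericVector& upv, const NumericVector& fwd,
                double s, int W, int H, const NumericVector& bg) {
  const int nf = F.nrow(), nv = V.nrow();
  NumericVector img(H * W * 3);
  NumericMatrix depth(H, W);
  std::fill(depth.begin(), depth.end(), R_PosInf);
  for (int ch = 0; ch < 3; ++ch)
    for (int p = 0; p < H * W; ++p) img[p + ch * H * W] = bg[ch];

  // project all vertices once
  std::vector<double> px(nv), py(nv);
  std::vector<bool> front(nv);
  for (int i = 0; i < nv; ++i) {
    double d[3] = { V(i, 0) - pos[0], V(i, 1) - pos[1], V(i, 2) - pos[2] };
    double zf = vdot(d, &fwd[0]);
    front[i] = zf > 1e-9;
    if (front[i]) {
      px[i] = W / 2.0 + vdot(d, &right[0]) / (zf * s);
      py[i] = H / 2.0 - vdot(d, &upv[0]) / (zf * s);
    }
  }

  double o[3] = { pos[0], pos[1], pos[2] };
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
    if (!front[i0] || !front[i1] || !front[i2]) continue;
    double xmin = std::min(px[i0], std::min(px[i1], px[i2]));
    double xmax = std::max(px[i0], std::max(px[i1], px[i2]));
    double ymin = std::min(py[i0], std::min(py[i1], py[i2]));
    double ymax = std::max(py[i0], std::max(py[i1], py[i2]));
    int x0 = std::max(0, (int)std::floor(xmin - 0.5));
    int x1 = std::min(W - 1, (int)std::ceil(xmax - 0.5));
    int y0 = std::max(0, (int)std::floor(ymin - 0.5));
    int y1 = std::min(H - 1, (int)std::ceil(ymax - 0.5));
    if (x0 > x1 || y0 > y1) continue;
    double a[3], b[3], c[3];
    get_vertex(V, i0, a);
    get_vertex(V, i1, b);
    get_vertex(V, i2, c);
    for (int iy = y0; iy <= y1; ++iy) {
      for (int ix = x0; ix <= x1; ++ix) {
        double dx = (ix + 0.5) - W / 2.0;
        double dy = (iy + 0.5) - H / 2.0;
        double dir[3];
        for (int k = 0; k < 3; ++k)
          dir[k] = fwd[k] + right[k] * dx * s - upv[k] * dy * s;
        double n = vnorm(dir);
        for (int k = 0; k < 3; ++k) dir[k] /= n;
        double t, u, v;
        if (mt_hit(o, dir, a, b, c, t, u, v) && t < depth(iy, ix)) {
          depth(iy, ix) = t;
          double w0 = 1.0 - u - v;
          for (int ch = 0; ch < 3; ++ch)
            img[iy + H * ix + H * W * ch] =
              w0 * C(i0, ch) + u * C(i1, ch) + v * C(i2, ch);
        }
      }
    }
  }
  img.attr("dim") = IntegerVector::create(H, W, 3);
  return List::create(_["image"] = img, _["depth"] = depth);
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision
// Detection). region: 0 interior, 1/2/3 vertex a/b/c, 4 edge ab, 5 edge bc,
// 6 edge ca.
static inline void closest_pt_tri(const double* p, const double* a,
                                  const double* b, const double* c,
                                  double* out, int& region) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { region = 1; for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3];
  vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { region = 2; for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    region = 4;
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ab[k];
    return;
  }
  double cp[3];
  vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { region = 3; for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    region = 6;
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    region = 5;
    for (int k = 0; k < 3; ++k) out[k] = b[k] + t * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  region = 0;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// Closest surface points for a set of queries. border_vertex marks vertices
// lying on a boundary edge of the mesh; a correspondence is flagged on_border
// when the closest point falls on a vertex/edge made of border vertices.
// [[Rcpp::export]]
List cpp_closest_points(const NumericMatrix& Q, const NumericMatrix& V,
                        const IntegerMatrix& F,
                        const LogicalVector& border_vertex) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix point(nq, 3);
  NumericVector dist(nq);
  IntegerVector tri(nq);
  LogicalVector on_border(nq);
  // flatten triangle vertices and precompute centroid + bounding radius for
  // a conservative early-out (results identical to the plain loop)
  std::vector<double> tv(9 * nf), ctr(3 * nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    get_vertex(V, F(f, 0), &tv[9 * f]);
    get_vertex(V, F(f, 1), &tv[9 * f + 3]);
    get_vertex(V, F(f, 2), &tv[9 * f + 6]);
    double r2 = 0;
    for (int k = 0; k < 3; ++k)
      ctr[3 * f + k] = (tv[9 * f + k] + tv[9 * f + 3 + k] + tv[9 * f + 6 + k]) / 3.0;
    for (int j = 0; j < 3; ++j) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double dd = tv[9 * f + 3 * j + k] - ctr[3 * f + k];
        d2 += dd * dd;
      }
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  for (int q = 0; q < nq; ++q) {
    double p[3] = { Q(q, 0), Q(q, 1), Q(q, 2) };
    double best = std::numeric_limits<double>::infinity();
    double bestpt[3] = { 0, 0, 0 };
    int best_f = -1, best_region = 0;
    for (int f = 0; f < nf; ++f) {
      double dc0 = p[0] - ctr[3 * f], dc1 = p[1] - ctr[3 * f + 1],
             dc2 = p[2] - ctr[3 * f + 2];
      double dcen = std::sqrt(dc0 * dc0 + dc1 * dc1 + dc2 * dc2);
      double lb = dcen - rad[f];
      if (lb > 0 && lb * lb >= best) continue;
      const double *a = &tv[9 * f], *b = &tv[9 * f + 3], *c = &tv[9 * f + 6];
      double out[3];
      int region;
      closest_pt_tri(p, a, b, c, out, region);
      double d2 = (p[0] - out[0]) * (p[0] - out[0]) +
                  (p[1] - out[1]) * (p[1] - out[1]) +
                  (p[2] - out[2]) * (p[2] - out[2]);
      if (d2 < best) {
        best = d2;
        best_f = f;
        best_region = region;
        for (int k = 0; k < 3; ++k) bestpt[k] = out[k];
      }
    }
    for (int k = 0; k < 3; ++k) point(q, k) = bestpt[k];
    dist[q] = std::sqrt(best);
    tri[q] = best_f + 1;
    bool bv0 = border_vertex[F(best_f, 0)], bv1 = border_vertex[F(best_f, 1)],
         bv2 = border_vertex[F(best_f, 2)];
    bool border = false;
    switch (best_region) {
      case 1: border = bv0; break;
      case 2: border = bv1; break;
      case 3: border = bv2; break;
      case 4: border = bv0 && bv1; break;
      case 5: border = bv1 && bv2; break;
      case 6: border = bv2 && bv0; break;
      default: border = false;
    }
    on_border[q] = border;
  }
  return List::create(_["point"] = point, _["distance"] = dist,
                      _["triangle"] = tri, _["on_border"] = on_border);
}

// Nearest point on the mesh to a half-line (used to snap silhouette-grazing
// landmark rays). For a ray that misses every triangle the closest mesh point
// lies on a triangle edge, so the edge/ray segment distance suffices; rays
// that do hit are handled by cast_ray beforehand.
// [[Rcpp::export]]
List cpp_ray_mesh_nearest(const NumericMatrix& V, const IntegerMatrix& F,
                          const NumericVector& origin,
                          const NumericVector& dir, double tmax) {
  const int nf = F.nrow();
  double best = std::numeric_limits<double>::infinity();
  double bestpt[3] = { 0, 0, 0 };
  int best_f = -1;
  double o[3] = { origin[0], origin[1], origin[2] };
  double d[3] = { dir[0], dir[1], dir[2] };
  for (int f = 0; f < nf; ++f) {
    double tv[9];
    get_vertex(V, F(f, 0), tv);
    get_vertex(V, F(f, 1), tv + 3);
    get_vertex(V, F(f, 2), tv + 6);
    for (int e = 0; e < 3; ++e) {
      const double* p0 = tv + 3 * e;
      const double* p1 = tv + 3 * ((e + 1) % 3);
      // closest approach between ray o + s*d (s in [0,tmax]) and segment
      // p0 + u*(p1-p0) (u in [0,1])
      double seg[3];
      vsub(p1, p0, seg);
      double w0[3];
      vsub(o, p0, w0);
      double A = vdot(d, d), B = vdot(d, seg), C = vdot(seg, seg);
      double D = vdot(d, w0), E = vdot(seg, w0);
      double den = A * C - B * B;
      double s, u;
      if (den < 1e-14) { s = 0.0; u = (C > 0) ? E / C : 0.0; }
      else { s = (B * E - C * D) / den; u = (A * E - B * D) / den; }
      if (u < 0) u = 0; else if (u > 1) u = 1;
      // re-project s for clamped u
      s = (vdot(seg, d) * u + vdot(d, p0) - vdot(d, o)) / A;
      if (s < 0) s = 0; else if (s > tmax) s = tmax;
      double qp[3], mp[3];
      for (int k = 0; k < 3; ++k) {
        qp[k] = o[k] + s * d[k];
        mp[k] = p0[k] + u * seg[k];
      }
      double dd = (qp[0] - mp[0]) * (qp[0] - mp[0]) +
                  (qp[1] - mp[1]) * (qp[1] - mp[1]) +
                  (qp[2] - mp[2]) * (qp[2] - mp[2]);
      if (dd < best) {
        best = dd;
        best_f = f;
        for (int k = 0; k < 3; ++k) bestpt[k] = mp[k];
      }
    }
  }
  return List::create(
    _["point"] = NumericVector::create(bestpt[0], bestpt[1], bestpt[2]),
    _["distance"] = std::sqrt(best), _["triangle"] = best_f + 1);
}

// Area-weighted per-vertex normals (cross products accumulated, then
// normalized; isolated vertices get a zero normal).
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(const NumericMatrix& V,
                                 const IntegerMatrix& F) {
  const int nv = V.nrow(), nf = F.nrow();
  NumericMatrix N(nv, 3);
  for (int f = 0; f < nf; ++f) {
    double a[3], b[3], c[3], e1[3], e2[3], n[3];
    get_vertex(V, F(f, 0), a);
    get_vertex(V, F(f, 1), b);
    get_vertex(V, F(f, 2), c);
    vsub(b, a, e1);
    vsub(c, a, e2);
    vcross(e1, e2, n);
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k) N(F(f, j), k) += n[k];
  }
  for (int i = 0; i < nv; ++i) {
    double n[3] = { N(i, 0), N(i, 1), N(i, 2) };
    double len = vnorm(n);
    if (len > 1e-14)
      for (int k = 0; k < 3; ++k) N(i, k) /= len;
  }
  return N;
}
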