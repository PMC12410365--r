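// Lagrangian tracking core: search-box host location on tetrahedral meshes,
// forward-Euler advection with barycentric interpolation, outlet detection
// and specular wall reflection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Uniform Cartesian search boxes over the mesh bounding box; every element
// is listed in every box its bounding box overlaps (CSR layout).
// [[Rcpp::export]]
List build_search_boxes(const arma::mat& nodes, const arma::imat& tets,
                        const arma::ivec& nb, const arma::vec& lo,
                        const arma::vec& hi) {
  const int nx = nb[0], ny = nb[1], nz = nb[2];
  const int nbox = nx * ny * nz;
  const arma::uword M = tets.n_rows;
  arma::vec span = hi - lo;
  for (int d = 0; d < 3; ++d) if (span[d] <= 0) span[d] = 1.0;
  std::vector<std::vector<int>> boxes(nbox);
  auto clampi = [](int v, int n) { return std::max(0, std::min(v, n - 1)); };
  for (arma::uword e = 0; e < M; ++e) {
    double bx0 = arma::datum::inf, bx1 = -arma::datum::inf;
    double by0 = bx0, by1 = bx1, bz0 = bx0, bz1 = bx1;
    for (int v = 0; v < 4; ++v) {
      const int nid = tets(e, v);
      bx0 = std::min(bx0, nodes(nid, 0)); bx1 = std::max(bx1, nodes(nid, 0));
      by0 = std::min(by0, nodes(nid, 1)); by1 = std::max(by1, nodes(nid, 1));
      bz0 = std::min(bz0, nodes(nid, 2)); bz1 = std::max(bz1, nodes(nid, 2));
    }
    int i0 = clampi((int) std::floor((bx0 - lo[0]) / span[0] * nx), nx);
    int i1 = clampi((int) std::floor((bx1 - lo[0]) / span[0] * nx), nx);
    int j0 = clampi((int) std::floor((by0 - lo[1]) / span[1] * ny), ny);
    int j1 = clampi((int) std::floor((by1 - lo[1]) / span[1] * ny), ny);
    int k0 = clampi((int) std::floor((bz0 - lo[2]) / span[2] * nz), nz);
    int k1 = clampi((int) std::floor((bz1 - lo[2]) / span[2] * nz), nz);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k)
          boxes[(k * ny + j) * nx + i].push_back((int) e);
  }
  arma::ivec ptr(nbox + 1);
  ptr[0] = 0;
  for (int b = 0; b < nbox; ++b) ptr[b + 1] = ptr[b] + (int) boxes[b].size();
  arma::ivec elems(ptr[nbox] > 0 ? ptr[nbox] : 1);
  for (int b = 0, pos = 0; b < nbox; ++b)
    for (size_t i = 0; i < boxes[b].size(); ++i) elems[pos++] = boxes[b][i];
  return List::create(_["ptr"] = ptr, _["elems"] = elems);
}

struct MeshRef {
  const arma::mat& nodes;
  const arma::imat& tets;
  const arma::mat& tinv;   // M x 9 row-major inverse edge matrices
  const arma::ivec& ptr;
  const arma::ivec& elems;
  const arma::ivec& nb;
  const arma::vec& lo;
  const arma::vec& span;
  double tol;
};

static inline int box_of(const MeshRef& m, const double* x) {
  int i = (int) std::floor((x[0] - m.lo[0]) / m.span[0] * m.nb[0]);
  int j = (int) std::floor((x[1] - m.lo[1]) / m.span[1] * m.nb[1]);
  int k = (int) std::floor((x[2] - m.lo[2]) / m.span[2] * m.nb[2]);
  if (i < 0 || j < 0 || k < 0 || i >= m.nb[0] || j >= m.nb[1] || k >= m.nb[2])
    return -1;
  return (k * m.nb[1] + j) * m.nb[0] + i;
}

// Barycentric coordinates of x in tet e; returns minimum coordinate.
static inline double bary_min(const MeshRef& m, int e, const double* x,
                              double* w) {
  const int n0 = m.tets(e, 0);
  const double dx = x[0] - m.nodes(n0, 0);
  const double dy = x[1] - m.nodes(n0, 1);
  const double dz = x[2] - m.nodes(n0, 2);
  const double* Ti = m.tinv.colptr(0); // column-major arma: use row access
  // tinv stored row e: entries (0..8) row-major 3x3
  double a0 = m.tinv(e, 0) * dx + m.tinv(e, 1) * dy + m.tinv(e, 2) * dz;
  double a1 = m.tinv(e, 3) * dx + m.tinv(e, 4) * dy + m.tinv(e, 5) * dz;
  double a2 = m.tinv(e, 6) * dx + m.tinv(e, 7) * dy + m.tinv(e, 8) * dz;
  (void) Ti;
  w[1] = a0; w[2] = a1; w[3] = a2; w[0] = 1.0 - a0 - a1 - a2;
  double mn = w[0];
  for (int i = 1; i < 4; ++i) mn = std::min(mn, w[i]);
  return mn;
}

// Host element of x: candidates of the search box, all barycentric
// coordinates >= -tol; ties (shared faces) resolved by lowest element id
// because candidates are scanned in ascending id order within a box.
static int locate_host_impl(const MeshRef& m, const double* x, double* w) {
  const int b = box_of(m, x);
  if (b < 0) return -1;
  int best = -1;
  for (int q = m.ptr[b]; q < m.ptr[b + 1]; ++q) {
    const int e = m.elems[q];
    double wt[4];
    if (bary_min(m, e, x, wt) >= -m.tol) {
      if (best < 0 || e < best) {
        best = e;
        for (int i = 0; i < 4; ++i) w[i] = wt[i];
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector locate_hosts_cpp(const arma::mat& points, const arma::mat& nodes,
                               const arma::imat& tets, const arma::mat& tinv,
                               const arma::ivec& ptr, const arma::ivec& elems,
                               const arma::ivec& nb, const arma::vec& lo,
                               const arma::vec& hi, double tol) {
  arma::vec span = hi - lo;
  for (int d = 0; d < 3; ++d) if (span[d] <= 0) span[d] = 1.0;
  MeshRef m{nodes, tets, tinv, ptr, elems, nb, lo, span, tol};
  const arma::uword n = points.n_rows;
  IntegerVector out(n);
  double w[4];
  for (arma::uword i = 0; i < n; ++i) {
    double x[3] = {points(i, 0), points(i, 1), points(i, 2)};
    out[i] = locate_host_impl(m, x, w) + 1; // 1-based, 0 = none
  }
  return out;
}

// Moller-Trumbore segment/triangle intersection; returns parameter s in
// [0,1] along p0->p1 or -1.
static double seg_tri_intersect(const double* p0, const double* p1,
                                const double* v0, const double* v1,
                                const double* v2) {
  double dir[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double e1[3] = {v1[0] - v0[0], v1[1] - v0[1], v1[2] - v0[2]};
  double e2[3] = {v2[0] - v0[0], v2[1] - v0[1], v2[2] - v0[2]};
  double h[3] = {dir[1] * e2[2] - dir[2] * e2[1],
                 dir[2] * e2[0] - dir[0] * e2[2],
                 dir[0] * e2[1] - dir[1] * e2[0]};
  double a = e1[0] * h[0] + e1[1] * h[1] + e1[2] * h[2];
  if (std::fabs(a) < 1e-300) return -1;
  double f = 1.0 / a;
  double s[3] = {p0[0] - v0[0], p0[1] - v0[1], p0[2] - v0[2]};
  double u = f * (s[0] * h[0] + s[1] * h[1] + s[2] * h[2]);
  if (u < -1e-10 || u > 1 + 1e-10) return -1;
  double q[3] = {s[1] * e1[2] - s[2] * e1[1],
                 s[2] * e1[0] - s[0] * e1[2],
                 s[0] * e1[1] - s[1] * e1[0]};
  double v = f * (dir[0] * q[0] + dir[1] * q[1] + dir[2] * q[2]);
  if (v < -1e-10 || u + v > 1 + 1e-10) return -1;
  double t = f * (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]);
  if (t < -1e-10 || t > 1 + 1e-10) return -1;
  return std::max(0.0, std::min(1.0, t));
}

// Specular reflection about a triangle's plane: the remaining displacement
// beyond the crossing point is mirrored so incidence angle = reflection
// angle and total path length is preserved.
static void reflect_about_plane(const double* pc, const double* pa,
                                const double* v0, const double* v1,
                                const double* v2, double* out) {
  double e1[3] = {v1[0] - v0[0], v1[1] - v0[1], v1[2] - v0[2]};
  double e2[3] = {v2[0] - v0[0], v2[1] - v0[1], v2[2] - v0[2]};
  double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                 e1[2] * e2[0] - e1[0] * e2[2],
                 e1[0] * e2[1] - e1[1] * e2[0]};
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (nn <= 0) { out[0] = pc[0]; out[1] = pc[1]; out[2] = pc[2]; return; }
  for (int d = 0; d < 3; ++d) n[d] /= nn;
  double rem[3] = {pa[0] - pc[0], pa[1] - pc[1], pa[2] - pc[2]};
  double rn = rem[0] * n[0] + rem[1] * n[1] + rem[2] * n[2];
  for (int d = 0; d < 3; ++d) out[d] = pc[d] + rem[d] - 2.0 * rn * n[d];
}

// [[Rcpp::export]]
List reflect_segment_cpp(const arma::vec& prev, const arma::vec& attempted,
                         const arma::mat& tri_v0, const arma::mat& tri_v1,
                         const arma::mat& tri_v2) {
  const arma::uword nt = tri_v0.n_rows;
  double p0[3] = {prev[0], prev[1], prev[2]};
  double p1[3] = {attempted[0], attempted[1], attempted[2]};
  double best_s = 2.0;
  int best = -1;
  for (arma::uword i = 0; i < nt; ++i) {
    double v0[3] = {tri_v0(i, 0), tri_v0(i, 1), tri_v0(i, 2)};
    double v1[3] = {tri_v1(i, 0), tri_v1(i, 1), tri_v1(i, 2)};
    double v2[3] = {tri_v2(i, 0), tri_v2(i, 1), tri_v2(i, 2)};
    double s = seg_tri_intersect(p0, p1, v0, v1, v2);
    if (s >= 0 && s < best_s) { best_s = s; best = (int) i; }
  }
  if (best < 0) {
    return List::create(_["hit"] = false);
  }
  double pc[3];
  for (int d = 0; d < 3; ++d) pc[d] = p0[d] + best_s * (p1[d] - p0[d]);
  double v0[3] = {tri_v0(best, 0), tri_v0(best, 1), tri_v0(best, 2)};
  double v1[3] = {tri_v1(best, 0), tri_v1(best, 1), tri_v1(best, 2)};
  double v2[3] = {tri_v2(best, 0), tri_v2(best, 1), tri_v2(best, 2)};
  double out[3];
  reflect_about_plane(pc, p1, v0, v1, v2, out);
  return List::create(_["hit"] = true, _["triangle"] = best + 1,
                      _["crossing"] = NumericVector::create(pc[0], pc[1], pc[2]),
                      _["corrected"] = NumericVector::create(out[0], out[1], out[2]));
}

// One forward-Euler advection step for all active particles.
// status: 0 active, 1 exited via outlet, 2 frozen (reflection failure).
// Velocities/gradients are interpolated at the CURRENT position (recorded),
// the position is advanced, exits and wall crossings are handled.
// [[Rcpp::export]]
List advect_step_cpp(arma::mat& pos, arma::ivec& host, arma::ivec& status,
                     const arma::mat& u_nodal, const arma::mat& grad_nodal,
                     const arma::mat& nodes, const arma::imat& tets,
                     const arma::mat& tinv, const arma::ivec& ptr,
                     const arma::ivec& elems, const arma::ivec& nb,
                     const arma::vec& lo, const arma::vec& hi,
                     const arma::imat& wall_faces, const arma::ivec& wn_ptr,
                     const arma::ivec& wn_faces, const arma::ivec& wall_node_ids,
                     const arma::imat& outlet_faces, double dt, double tol,
                     bool want_grad) {
  arma::vec span = hi - lo;
  for (int d = 0; d < 3; ++d) if (span[d] <= 0) span[d] = 1.0;
  MeshRef m{nodes, tets, tinv, ptr, elems, nb, lo, span, tol};
  const arma::uword n = pos.n_rows;
  arma::mat vel(n, 3, arma::fill::zeros);
  arma::mat grad;
  if (want_grad) grad.zeros(n, 9);
  int n_frozen = 0;
  for (arma::uword i = 0; i < n; ++i) {
    if (status[i] != 0) continue;
    double x[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double w[4];
    int h = host[i] - 1;
    if (h >= 0) {
      if (bary_min(m, h, x, w) < -m.tol) h = -1;
    }
    if (h < 0) h = locate_host_impl(m, x, w);
    if (h < 0) { status[i] = 2; ++n_frozen; continue; }
    host[i] = h + 1;
    double u[3] = {0, 0, 0};
    for (int v = 0; v < 4; ++v) {
      const int nid = m.tets(h, v);
      for (int d = 0; d < 3; ++d) u[d] += w[v] * u_nodal(nid, d);
    }
    for (int d = 0; d < 3; ++d) vel(i, d) = u[d];
    if (want_grad) {
      for (int v = 0; v < 4; ++v) {
        const int nid = m.tets(h, v);
        for (int d = 0; d < 9; ++d) grad(i, d) += w[v] * grad_nodal(nid, d);
      }
    }
    double xn[3] = {x[0] + dt * u[0], x[1] + dt * u[1], x[2] + dt * u[2]};
    double wn[4];
    int hn = -1;
    if (bary_min(m, h, xn, wn) >= -m.tol) hn = h;
    else hn = locate_host_impl(m, xn, wn);
    if (hn >= 0) {
      pos(i, 0) = xn[0]; pos(i, 1) = xn[1]; pos(i, 2) = xn[2];
      host[i] = hn + 1;
      continue;
    }
    // no host: outlet first (far fewer faces than the wall)
    bool exited = false;
    for (arma::uword f = 0; f < outlet_faces.n_rows && !exited; ++f) {
      double v0[3], v1[3], v2[3];
      for (int d = 0; d < 3; ++d) {
        v0[d] = nodes(outlet_faces(f, 0), d);
        v1[d] = nodes(outlet_faces(f, 1), d);
        v2[d] = nodes(outlet_faces(f, 2), d);
      }
      if (seg_tri_intersect(x, xn, v0, v1, v2) >= 0) exited = true;
    }
    if (exited) {
      pos(i, 0) = xn[0]; pos(i, 1) = xn[1]; pos(i, 2) = xn[2];
      status[i] = 1;
      continue;
    }
    // wall reflection: closest wall node -> first-ring faces -> intersection
    int best_node = -1;
    double best_d = arma::datum::inf;
    for (arma::uword k = 0; k < wall_node_ids.n_elem; ++k) {
      const int nid = wall_node_ids[k];
      const double ddx = xn[0] - nodes(nid, 0);
      const double ddy = xn[1] - nodes(nid, 1);
      const double ddz = xn[2] - nodes(nid, 2);
      const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best_d) { best_d = d2; best_node = (int) k; }
    }
    bool corrected = false;
    if (best_node >= 0) {
      double best_s = 2.0; int best_f = -1;
      for (int q = wn_ptr[best_node]; q < wn_ptr[best_node + 1]; ++q) {
        const int f = wn_faces[q];
        double v0[3], v1[3], v2[3];
        for (int d = 0; d < 3; ++d) {
          v0[d] = nodes(wall_faces(f, 0), d);
          v1[d] = nodes(wall_faces(f, 1), d);
          v2[d] = nodes(wall_faces(f, 2), d);
        }
        double s = seg_tri_intersect(x, xn, v0, v1, v2);
        if (s >= 0 && s < best_s) { best_s = s; best_f = f; }
      }
      if (best_f < 0) {
        // fallback: nearest first-ring face by centroid, projection-style
        double bd = arma::datum::inf;
        for (int q = wn_ptr[best_node]; q < wn_ptr[best_node + 1]; ++q) {
          const int f = wn_faces[q];
          double cx = 0, cy = 0, cz = 0;
          for (int v = 0; v < 3; ++v) {
            cx += nodes(wall_faces(f, v), 0) / 3.0;
            cy += nodes(wall_faces(f, v), 1) / 3.0;
            cz += nodes(wall_faces(f, v), 2) / 3.0;
          }
          const double d2 = (xn[0] - cx) * (xn[0] - cx) +
            (xn[1] - cy) * (xn[1] - cy) + (xn[2] - cz) * (xn[2] - cz);
          if (d2 < bd) { bd = d2; best_f = f; }
        }
        best_s = 0.5;
      }
      if (best_f >= 0) {
        double pc[3];
        for (int d = 0; d < 3; ++d) pc[d] = x[d] + best_s * (xn[d] - x[d]);
        double v0[3], v1[3], v2[3];
        for (int d = 0; d < 3; ++d) {
          v0[d] = nodes(wall_faces(best_f, 0), d);
          v1[d] = nodes(wall_faces(best_f, 1), d);
          v2[d] = nodes(wall_faces(best_f, 2), d);
        }
        double xr[3];
        reflect_about_plane(pc, xn, v0, v1, v2, xr);
        double wr[4];
        int hr = locate_host_impl(m, xr, wr);
        if (hr >= 0) {
          pos(i, 0) = xr[0]; pos(i, 1) = xr[1]; pos(i, 2) = xr[2];
          host[i] = hr + 1;
          corrected = true;
        } else {
          pos(i, 0) = pc[0]; pos(i, 1) = pc[1]; pos(i, 2) = pc[2];
          status[i] = 2;
          ++n_frozen;
          corrected = true;
        }
      }
    }
    if (!corrected) { status[i] = 2; ++n_frozen; }
  }
  return List::create(_["vel"] = vel, _["grad"] = grad,
                      _["n_frozen"] = n_frozen);
}
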