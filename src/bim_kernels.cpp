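// Boundary-integral kernels for the membrane solver.
//
// Singular surface integrals use a rotated-pole quadrature: for each
// collocation (target) point the quadrature lattice is a Gauss-Legendre x
// uniform grid on the parameter sphere whose pole coincides with the
// target, so the solid-angle measure sin(theta') cancels the 1/r Stokeslet
// singularity. Fields are band-limited spherical-harmonic expansions;
// evaluation at the rotated nodes uses per-latitude synthesis matrices
// (precomputed in R) combined with a z-rotation applied in coefficient
// space (a phase shift of the order-m modes).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Apply a z-rotation by angle alpha to real-SH coefficient columns:
// the rotated expansion evaluated at x equals the original at Rz(alpha) x.
static void rotate_z_coeffs(const arma::mat& C, arma::mat& out,
                            const arma::ivec& mdeg, const arma::ivec& ctype,
                            const arma::ivec& partner, double alpha) {
  out = C;
  const arma::uword n = C.n_rows;
  for (arma::uword i = 0; i < n; ++i) {
    if (ctype[i] == 1) { // cosine entry; partner is the sine entry
      const double cma = std::cos(mdeg[i] * alpha);
      const double sma = std::sin(mdeg[i] * alpha);
      const arma::uword j = partner[i];
      for (arma::uword k = 0; k < C.n_cols; ++k) {
        const double c = C(i, k), s = C(j, k);
        out(i, k) = cma * c + sma * s;
        out(j, k) = -sma * c + cma * s;
      }
    }
  }
}

// Evaluate stacked coefficient columns at the rotated-pole lattice of every
// target: returns a cube (Nq x ncols x Ntargets).
// [[Rcpp::export]]
arma::cube bim_rotate_fields(const List& Ms, const arma::mat& C,
                             const arma::ivec& latidx, const arma::vec& phi0,
                             const arma::ivec& mdeg, const arma::ivec& ctype,
                             const arma::ivec& partner) {
  std::vector<arma::mat> Mlist;
  for (int i = 0; i < Ms.size(); ++i) Mlist.push_back(as<arma::mat>(Ms[i]));
  const arma::uword N = latidx.n_elem;
  const arma::uword Nq = Mlist[0].n_rows;
  arma::cube out(Nq, C.n_cols, N);
  arma::mat Crot;
  for (arma::uword t = 0; t < N; ++t) {
    rotate_z_coeffs(C, Crot, mdeg, ctype, partner, phi0[t]);
    out.slice(t) = Mlist[latidx[t] - 1] * Crot;
  }
  return out;
}

// Single-layer (Stokeslet) and subtracted double-layer (stresslet)
// integrals at every collocation point.
//   geo slice t: columns 0:2 surface position x, 3:5 vector area density
//   wv = (x_theta x x_phi)/sin(theta), 6:8 single-layer density f.
//   sl[t]  = int f_i(x) G_ij(x, x0_t) dS
//   dl[t]  = int (u_i(x) - u_i(x0_t)) T_ijk(x, x0_t) n_k(x) dS
// [[Rcpp::export]]
List bim_layers(const arma::cube& geo, const List& Ms, const arma::mat& Cu,
                const arma::mat& x0, const arma::mat& u0, const arma::vec& wq,
                const arma::ivec& latidx, const arma::vec& phi0,
                const arma::ivec& mdeg, const arma::ivec& ctype,
                const arma::ivec& partner, bool do_sl, bool do_dl) {
  const arma::uword N = x0.n_rows;
  const arma::uword Nq = geo.n_rows;
  arma::mat SL(N, 3, arma::fill::zeros), DL(N, 3, arma::fill::zeros);
  std::vector<arma::mat> Mlist;
  if (do_dl) {
    for (int i = 0; i < Ms.size(); ++i) Mlist.push_back(as<arma::mat>(Ms[i]));
  }
  arma::mat Crot, U;
  for (arma::uword t = 0; t < N; ++t) {
    const arma::mat& S = geo.slice(t);
    if (do_dl) {
      rotate_z_coeffs(Cu, Crot, mdeg, ctype, partner, phi0[t]);
      U = Mlist[latidx[t] - 1] * Crot;
    }
    const double x0x = x0(t, 0), x0y = x0(t, 1), x0z = x0(t, 2);
    double sl0 = 0, sl1 = 0, sl2 = 0, dl0 = 0, dl1 = 0, dl2 = 0;
    for (arma::uword k = 0; k < Nq; ++k) {
      const double rx = S(k, 0) - x0x, ry = S(k, 1) - x0y, rz = S(k, 2) - x0z;
      const double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 <= 0) continue;
      const double rn = std::sqrt(r2);
      const double wvx = S(k, 3), wvy = S(k, 4), wvz = S(k, 5);
      if (do_sl) {
        const double wt = wq[k] * std::sqrt(wvx * wvx + wvy * wvy + wvz * wvz);
        const double fx = S(k, 6), fy = S(k, 7), fz = S(k, 8);
        const double fr = fx * rx + fy * ry + fz * rz;
        const double c1 = wt / rn, c2 = wt * fr / (r2 * rn);
        sl0 += c1 * fx + c2 * rx;
        sl1 += c1 * fy + c2 * ry;
        sl2 += c1 * fz + c2 * rz;
      }
      if (do_dl) {
        const double dux = U(k, 0) - u0(t, 0);
        const double duy = U(k, 1) - u0(t, 1);
        const double duz = U(k, 2) - u0(t, 2);
        const double dur = dux * rx + duy * ry + duz * rz;
        const double rv = rx * wvx + ry * wvy + rz * wvz;
        const double c = -6.0 * wq[k] * dur * rv / (r2 * r2 * rn);
        dl0 += c * rx;
        dl1 += c * ry;
        dl2 += c * rz;
      }
    }
    SL(t, 0) = sl0; SL(t, 1) = sl1; SL(t, 2) = sl2;
    DL(t, 0) = dl0; DL(t, 1) = dl1; DL(t, 2) = dl2;
  }
  return List::create(_["sl"] = SL, _["dl"] = DL);
}

// Fixed-point (Picard) solve of the boundary-integral equation for the
// interfacial velocity at viscosity contrast lambda != 1:
//   u = (1+lambda)/2 * (b + beta * K[u]),
//   K[u](x0) = int (u(x) - u(x0)) T(x, x0) n(x) dS,
// with beta = (1-lambda)/(4 pi (1+lambda)). The synthesis matrices are
// converted once; each iteration only re-synthesizes u at the rotated
// lattices of every target.
// [[Rcpp::export]]
List bim_picard(const List& Ms, const arma::cube& geo, const arma::mat& x0,
                const arma::mat& b, const arma::mat& YtW, const arma::mat& Y,
                const arma::mat& u_init, const arma::vec& wq,
                const arma::ivec& latidx, const arma::vec& phi0,
                const arma::ivec& mdeg, const arma::ivec& ctype,
                const arma::ivec& partner, double lambda, double tol,
                int maxit) {
  std::vector<arma::mat> Mlist;
  for (int i = 0; i < Ms.size(); ++i) Mlist.push_back(as<arma::mat>(Ms[i]));
  const arma::uword N = b.n_rows;
  const arma::uword Nq = geo.n_rows;
  const double beta = (1.0 - lambda) / (4.0 * arma::datum::pi * (1.0 + lambda));
  const double pref = (1.0 + lambda) / 2.0;
  arma::mat u = u_init;
  const double scale = std::max(arma::abs(b).max(), 1e-300);
  bool converged = false;
  int it = 0;
  double delta = arma::datum::inf;
  arma::mat Cu, Crot, U, u0, K(N, 3);
  while (it < maxit) {
    ++it;
    Cu = YtW * u;
    u0 = Y * Cu;
    for (arma::uword t = 0; t < N; ++t) {
      rotate_z_coeffs(Cu, Crot, mdeg, ctype, partner, phi0[t]);
      U = Mlist[latidx[t] - 1] * Crot;
      const arma::mat& S = geo.slice(t);
      const double px = x0(t, 0), py = x0(t, 1), pz = x0(t, 2);
      const double ux0 = u0(t, 0), uy0 = u0(t, 1), uz0 = u0(t, 2);
      double k0 = 0, k1 = 0, k2 = 0;
      for (arma::uword k = 0; k < Nq; ++k) {
        const double rx = S(k, 0) - px, ry = S(k, 1) - py, rz = S(k, 2) - pz;
        const double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 <= 0) continue;
        const double rn = std::sqrt(r2);
        const double dux = U(k, 0) - ux0, duy = U(k, 1) - uy0,
          duz = U(k, 2) - uz0;
        const double dur = dux * rx + duy * ry + duz * rz;
        const double rv = rx * S(k, 3) + ry * S(k, 4) + rz * S(k, 5);
        const double c = -6.0 * wq[k] * dur * rv / (r2 * r2 * rn);
        k0 += c * rx; k1 += c * ry; k2 += c * rz;
      }
      K(t, 0) = k0; K(t, 1) = k1; K(t, 2) = k2;
    }
    arma::mat u_new = pref * (b + beta * K);
    delta = arma::abs(u_new - u).max() / scale;
    u = u_new;
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["u"] = u, _["iterations"] = it,
                      _["converged"] = converged, _["delta"] = delta);
}

// Plain (non-singular) layer potentials at arbitrary off-surface targets,
// quadrature directly on a collocation lattice of the surface.
//   xs: quadrature-point positions, wv: vector area density, wq: solid-angle
//   weights, f: single-layer density, us: double-layer density at the nodes.
// [[Rcpp::export]]
List bim_layers_offsurf(const arma::mat& xs, const arma::mat& wv,
                        const arma::vec& wq, const arma::mat& f,
                        const arma::mat& us, const arma::mat& targets,
                        bool do_sl, bool do_dl) {
  const arma::uword N = targets.n_rows, Nq = xs.n_rows;
  arma::mat SL(N, 3, arma::fill::zeros), DL(N, 3, arma::fill::zeros);
  for (arma::uword t = 0; t < N; ++t) {
    double sl0 = 0, sl1 = 0, sl2 = 0, dl0 = 0, dl1 = 0, dl2 = 0;
    for (arma::uword k = 0; k < Nq; ++k) {
      const double rx = xs(k, 0) - targets(t, 0);
      const double ry = xs(k, 1) - targets(t, 1);
      const double rz = xs(k, 2) - targets(t, 2);
      const double r2 = rx * rx + ry * ry + rz * rz;
      const double rn = std::sqrt(r2);
      if (do_sl) {
        const double wt = wq[k] * std::sqrt(wv(k, 0) * wv(k, 0) +
                                            wv(k, 1) * wv(k, 1) +
                                            wv(k, 2) * wv(k, 2));
        const double fr = f(k, 0) * rx + f(k, 1) * ry + f(k, 2) * rz;
        const double c1 = wt / rn, c2 = wt * fr / (r2 * rn);
        sl0 += c1 * f(k, 0) + c2 * rx;
        sl1 += c1 * f(k, 1) + c2 * ry;
        sl2 += c1 * f(k, 2) + c2 * rz;
      }
      if (do_dl) {
        const double ur = us(k, 0) * rx + us(k, 1) * ry + us(k, 2) * rz;
        const double rv = rx * wv(k, 0) + ry * wv(k, 1) + rz * wv(k, 2);
        const double c = -6.0 * wq[k] * ur * rv / (r2 * r2 * rn);
        dl0 += c * rx; dl1 += c * ry; dl2 += c * rz;
      }
    }
    SL(t, 0) = sl0; SL(t, 1) = sl1; SL(t, 2) = sl2;
    DL(t, 0) = dl0; DL(t, 1) = dl1; DL(t, 2) = dl2;
  }
  return List::create(_["sl"] = SL, _["dl"] = DL);
}
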