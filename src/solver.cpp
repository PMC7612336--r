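// Explicit central-difference dynamics for 2D plane-strain quads
// (total-Lagrangian, single-point quadrature with stiffness hourglass
// control). Constitutive law: compressible neo-Hookean with optional
// Prony-series relaxation on the deviatoric Cauchy stress.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ElemGeom {
  double B0[4][2];   // reference shape-function gradients at centroid
  double gamma[4];   // hourglass base vector
  double V0;         // reference area
  double bb;         // sum_a B0_a . B0_a (for hourglass stiffness)
};

// plane-strain compressible neo-Hookean Cauchy stress
// sigma = mu J^{-5/3} dev3(B) + kappa (J-1) I, with B33 = 1
inline void neo_hookean(double F11, double F12, double F21, double F22,
                        double mu, double kappa,
                        double &sxx, double &syy, double &sxy,
                        double &dxx, double &dyy, double &dxy) {
  double J = F11 * F22 - F12 * F21;
  double Bxx = F11 * F11 + F12 * F12;
  double Byy = F21 * F21 + F22 * F22;
  double Bxy = F11 * F21 + F12 * F22;
  double trB3 = Bxx + Byy + 1.0;
  double c = mu * std::pow(J, -5.0 / 3.0);
  dxx = c * (Bxx - trB3 / 3.0);
  dyy = c * (Byy - trB3 / 3.0);
  dxy = c * Bxy;
  double p = kappa * (J - 1.0);
  sxx = dxx + p; syy = dyy + p; sxy = dxy;
}

inline void precompute_geom(const std::vector<double> &X,
                            const std::vector<double> &Y,
                            const IntegerMatrix &elems,
                            std::vector<ElemGeom> &geo, int &bad_elem) {
  const double xi[4] = {-1, 1, 1, -1};
  const double eta[4] = {-1, -1, 1, 1};
  const double hg[4] = {1, -1, 1, -1};
  int ne = elems.nrow();
  bad_elem = -1;
  for (int e = 0; e < ne; ++e) {
    double J11 = 0, J12 = 0, J21 = 0, J22 = 0;
    double xe[4], ye[4];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      xe[a] = X[n]; ye[a] = Y[n];
      J11 += xe[a] * xi[a] / 4.0;  J12 += xe[a] * eta[a] / 4.0;
      J21 += ye[a] * xi[a] / 4.0;  J22 += ye[a] * eta[a] / 4.0;
    }
    double dJ = J11 * J22 - J12 * J21;
    if (!(dJ > 0)) { bad_elem = e; return; }
    geo[e].V0 = 4.0 * dJ;
    double i11 = J22 / dJ, i12 = -J12 / dJ, i21 = -J21 / dJ, i22 = J11 / dJ;
    double hx = 0, hy = 0;
    geo[e].bb = 0;
    for (int a = 0; a < 4; ++a) {
      double b1 = xi[a] / 4.0 * i11 + eta[a] / 4.0 * i21;
      double b2 = xi[a] / 4.0 * i12 + eta[a] / 4.0 * i22;
      geo[e].B0[a][0] = b1; geo[e].B0[a][1] = b2;
      geo[e].bb += b1 * b1 + b2 * b2;
      hx += hg[a] * xe[a]; hy += hg[a] * ye[a];
    }
    for (int a = 0; a < 4; ++a)
      geo[e].gamma[a] = hg[a] - hx * geo[e].B0[a][0] - hy * geo[e].B0[a][1];
  }
}

inline double eig_max_sym2(double exx, double eyy, double exy) {
  double m = 0.5 * (exx + eyy);
  double d = 0.5 * (exx - eyy);
  return m + std::sqrt(d * d + exy * exy);
}

} // namespace

// Elastic internal nodal forces for a displacement state (no viscoelastic
// history). Returns an N x 2 matrix of internal forces (the forces the
// elements exert on the nodes carry the opposite sign).
// [[Rcpp::export]]
NumericMatrix cpp_internal_forces(NumericMatrix nodes, IntegerMatrix elems,
                                  NumericMatrix disp, NumericVector mu,
                                  NumericVector kappa, double hg_coef) {
  int nn = nodes.nrow(), ne = elems.nrow();
  std::vector<double> X(nn), Y(nn);
  for (int i = 0; i < nn; ++i) { X[i] = nodes(i, 0); Y[i] = nodes(i, 1); }
  std::vector<ElemGeom> geo(ne);
  int bad; precompute_geom(X, Y, elems, geo, bad);
  if (bad >= 0) stop("degenerate reference element %d", bad + 1);
  NumericMatrix f(nn, 2);
  for (int e = 0; e < ne; ++e) {
    double F11 = 0, F12 = 0, F21 = 0, F22 = 0, qx = 0, qy = 0;
    double xe[4], ye[4];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      xe[a] = X[n] + disp(n, 0); ye[a] = Y[n] + disp(n, 1);
      F11 += xe[a] * geo[e].B0[a][0]; F12 += xe[a] * geo[e].B0[a][1];
      F21 += ye[a] * geo[e].B0[a][0]; F22 += ye[a] * geo[e].B0[a][1];
      qx += geo[e].gamma[a] * xe[a];  qy += geo[e].gamma[a] * ye[a];
    }
    double sxx, syy, sxy, dxx, dyy, dxy;
    neo_hookean(F11, F12, F21, F22, mu[e], kappa[e], sxx, syy, sxy, dxx, dyy, dxy);
    double J = F11 * F22 - F12 * F21;
    // P = J sigma F^{-T}
    double iT11 = F22 / J, iT12 = -F21 / J, iT21 = -F12 / J, iT22 = F11 / J;
    double P11 = J * (sxx * iT11 + sxy * iT21);
    double P12 = J * (sxx * iT12 + sxy * iT22);
    double P21 = J * (sxy * iT11 + syy * iT21);
    double P22 = J * (sxy * iT12 + syy * iT22);
    double khg = hg_coef * mu[e] * geo[e].V0 * geo[e].bb;
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      f(n, 0) += geo[e].V0 * (P11 * geo[e].B0[a][0] + P12 * geo[e].B0[a][1]) +
                 khg * qx * geo[e].gamma[a];
      f(n, 1) += geo[e].V0 * (P21 * geo[e].B0[a][0] + P22 * geo[e].B0[a][1]) +
                 khg * qy * geo[e].gamma[a];
    }
  }
  return f;
}

// Cauchy stress history of a single material point following a prescribed
// deformation-gradient path (rows F11, F12, F21, F22), with a Prony series
// (possibly empty) acting on the deviatoric stress. Used as the constitutive
// oracle surface for relaxation tests.
// [[Rcpp::export]]
NumericMatrix cpp_stress_history(NumericMatrix Fpath, double dt, double mu,
                                 double kappa, NumericVector g,
                                 NumericVector tau) {
  int n = Fpath.nrow(), nv = g.size();
  NumericMatrix out(n, 3);
  std::vector<double> hxx(nv, 0), hyy(nv, 0), hxy(nv, 0);
  double pxx = 0, pyy = 0, pxy = 0;
  for (int k = 0; k < n; ++k) {
    double sxx, syy, sxy, dxx, dyy, dxy;
    neo_hookean(Fpath(k, 0), Fpath(k, 1), Fpath(k, 2), Fpath(k, 3),
                mu, kappa, sxx, syy, sxy, dxx, dyy, dxy);
    double gsum = 0, vxx = 0, vyy = 0, vxy = 0;
    for (int i = 0; i < nv; ++i) {
      if (k > 0) {
        double x = dt / tau[i], ex = std::exp(-x);
        double c = g[i] * (1.0 - ex) / x;
        hxx[i] = ex * hxx[i] + c * (dxx - pxx);
        hyy[i] = ex * hyy[i] + c * (dyy - pyy);
        hxy[i] = ex * hxy[i] + c * (dxy - pxy);
      } else {
        hxx[i] = g[i] * dxx; hyy[i] = g[i] * dyy; hxy[i] = g[i] * dxy;
      }
      gsum += g[i]; vxx += hxx[i]; vyy += hyy[i]; vxy += hxy[i];
    }
    pxx = dxx; pyy = dyy; pxy = dxy;
    double p = sxx - dxx;   // volumetric part (equal for xx, yy)
    out(k, 0) = (1 - gsum) * dxx + vxx + p;
    out(k, 1) = (1 - gsum) * dyy + vyy + p;
    out(k, 2) = (1 - gsum) * dxy + vxy;
  }
  return out;
}

// Explicit central-difference run with prescribed rigid skull motion.
// presc_dx/dy/th give skull translation (m) and rotation (rad) about
// (cx, cy) sampled at times k * dt_presc; the integration step itself is
// adaptive: every check_every steps the stable step is re-estimated from
// the CURRENT element geometry (large CSF shear collapses the element
// characteristic length well below its reference value). Returns
// per-element peak max-principal Green-Lagrange strain and strain rate.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix nodes, IntegerMatrix elems,
                  IntegerVector matid, NumericVector mu_m,
                  NumericVector kappa_m, NumericVector rho_m,
                  List prony_g, List prony_tau,
                  IntegerVector skull, NumericVector presc_dx,
                  NumericVector presc_dy, NumericVector presc_th,
                  double dt_presc, double t_end,
                  double cx, double cy, double dt0, double cfl_safety,
                  double damping, double hg_coef, int check_every) {
  int nn = nodes.nrow(), ne = elems.nrow();
  std::vector<double> X(nn), Y(nn);
  double xmax = 0;
  for (int i = 0; i < nn; ++i) {
    X[i] = nodes(i, 0); Y[i] = nodes(i, 1);
    double r = std::sqrt(X[i] * X[i] + Y[i] * Y[i]);
    if (r > xmax) xmax = r;
  }
  std::vector<ElemGeom> geo(ne);
  int bad; precompute_geom(X, Y, elems, geo, bad);
  if (bad >= 0) stop("degenerate reference element %d", bad + 1);

  // per-element materials
  int nmat = mu_m.size();
  std::vector<double> mu(ne), kap(ne);
  std::vector<int> mid(ne);
  int nv_max = 0;
  std::vector<std::vector<double>> gs(nmat), taus(nmat);
  for (int m = 0; m < nmat; ++m) {
    NumericVector g = prony_g[m], t = prony_tau[m];
    gs[m] = std::vector<double>(g.begin(), g.end());
    taus[m] = std::vector<double>(t.begin(), t.end());
    if ((int)gs[m].size() > nv_max) nv_max = gs[m].size();
  }
  for (int e = 0; e < ne; ++e) {
    mid[e] = matid[e] - 1;
    mu[e] = mu_m[mid[e]]; kap[e] = kappa_m[mid[e]];
  }

  // lumped nodal mass
  std::vector<double> mass(nn, 0.0);
  for (int e = 0; e < ne; ++e) {
    double m4 = rho_m[mid[e]] * geo[e].V0 / 4.0;
    for (int a = 0; a < 4; ++a) mass[elems(e, a) - 1] += m4;
  }

  std::vector<char> is_skull(nn, 0);
  for (int k = 0; k < skull.size(); ++k) is_skull[skull[k] - 1] = 1;

  std::vector<double> ux(nn, 0), uy(nn, 0), vx(nn, 0), vy(nn, 0);
  std::vector<double> fx(nn), fy(nn);
  std::vector<double> Exx(ne, 0), Eyy(ne, 0), Exy(ne, 0);
  std::vector<double> peak_E(ne, 0), peak_R(ne, 0);
  // viscoelastic state per element (up to nv_max terms)
  std::vector<double> hxx, hyy, hxy, pdx, pdy, pdxy;
  bool any_visc = false;
  for (int m = 0; m < nmat; ++m) if (!gs[m].empty()) any_visc = true;
  if (any_visc) {
    hxx.assign((size_t)ne * nv_max, 0); hyy.assign((size_t)ne * nv_max, 0);
    hxy.assign((size_t)ne * nv_max, 0);
    pdx.assign(ne, 0); pdy.assign(ne, 0); pdxy.assign(ne, 0);
  }

  // dilatational wave speed per material, for the running CFL estimate
  std::vector<double> cwave(nmat);
  for (int m = 0; m < nmat; ++m)
    cwave[m] = std::sqrt((kappa_m[m] + 4.0 * mu_m[m] / 3.0) / rho_m[m]);
  int np = presc_dx.size();

  int status = 0; double t_fail = NA_REAL;
  double t = 0, dt = dt0;
  long step = 0;
  long max_steps = (long)(400.0 * t_end / dt0) + 1000;
  while (t < t_end) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    bool first = (step == 0);
    for (int e = 0; e < ne; ++e) {
      double F11 = 0, F12 = 0, F21 = 0, F22 = 0, qx = 0, qy = 0;
      for (int a = 0; a < 4; ++a) {
        int nd = elems(e, a) - 1;
        double xa = X[nd] + ux[nd], ya = Y[nd] + uy[nd];
        F11 += xa * geo[e].B0[a][0]; F12 += xa * geo[e].B0[a][1];
        F21 += ya * geo[e].B0[a][0]; F22 += ya * geo[e].B0[a][1];
        qx += geo[e].gamma[a] * xa;  qy += geo[e].gamma[a] * ya;
      }
      // Green-Lagrange strain and its rate
      double exx = 0.5 * (F11 * F11 + F21 * F21 - 1.0);
      double eyy = 0.5 * (F12 * F12 + F22 * F22 - 1.0);
      double exy = 0.5 * (F11 * F12 + F21 * F22);
      double lam = eig_max_sym2(exx, eyy, exy);
      if (lam > peak_E[e]) peak_E[e] = lam;
      if (!first) {
        double rr = eig_max_sym2((exx - Exx[e]) / dt, (eyy - Eyy[e]) / dt,
                                 (exy - Exy[e]) / dt);
        if (rr > peak_R[e]) peak_R[e] = rr;
      }
      Exx[e] = exx; Eyy[e] = eyy; Exy[e] = exy;

      double sxx, syy, sxy, dxx, dyy, dxy;
      neo_hookean(F11, F12, F21, F22, mu[e], kap[e], sxx, syy, sxy,
                  dxx, dyy, dxy);
      const std::vector<double> &g = gs[mid[e]];
      if (!g.empty()) {
        const std::vector<double> &tv = taus[mid[e]];
        double gsum = 0, vxx_s = 0, vyy_s = 0, vxy_s = 0;
        for (size_t i = 0; i < g.size(); ++i) {
          size_t off = (size_t)e * nv_max + i;
          if (first) {
            hxx[off] = g[i] * dxx; hyy[off] = g[i] * dyy; hxy[off] = g[i] * dxy;
          } else {
            double x = dt / tv[i], ex = std::exp(-x);
            double c = g[i] * (1.0 - ex) / x;
            hxx[off] = ex * hxx[off] + c * (dxx - pdx[e]);
            hyy[off] = ex * hyy[off] + c * (dyy - pdy[e]);
            hxy[off] = ex * hxy[off] + c * (dxy - pdxy[e]);
          }
          gsum += g[i]; vxx_s += hxx[off]; vyy_s += hyy[off]; vxy_s += hxy[off];
        }
        pdx[e] = dxx; pdy[e] = dyy; pdxy[e] = dxy;
        double p = sxx - dxx;
        sxx = (1 - gsum) * dxx + vxx_s + p;
        syy = (1 - gsum) * dyy + vyy_s + p;
        sxy = (1 - gsum) * dxy + vxy_s;
      }

      double J = F11 * F22 - F12 * F21;
      double P11 = sxx * F22 - sxy * F12;   // J sigma F^{-T} expanded
      double P12 = -sxx * F21 + sxy * F11;
      double P21 = sxy * F22 - syy * F12;
      double P22 = -sxy * F21 + syy * F11;
      (void)J;
      double khg = hg_coef * mu[e] * geo[e].V0 * geo[e].bb;
      for (int a = 0; a < 4; ++a) {
        int nd = elems(e, a) - 1;
        fx[nd] += geo[e].V0 * (P11 * geo[e].B0[a][0] + P12 * geo[e].B0[a][1]) +
                  khg * qx * geo[e].gamma[a];
        fy[nd] += geo[e].V0 * (P21 * geo[e].B0[a][0] + P22 * geo[e].B0[a][1]) +
                  khg * qy * geo[e].gamma[a];
      }
    }

    // advance free nodes; impose rigid motion on skull nodes at t + dt
    double tq = (t + dt) / dt_presc;
    int i0 = (int)tq; double fr = tq - i0;
    if (i0 >= np - 1) { i0 = np - 2; fr = 1.0; }
    double th = presc_th[i0] + fr * (presc_th[i0 + 1] - presc_th[i0]);
    double dx = presc_dx[i0] + fr * (presc_dx[i0 + 1] - presc_dx[i0]);
    double dy = presc_dy[i0] + fr * (presc_dy[i0 + 1] - presc_dy[i0]);
    double ct = std::cos(th), st = std::sin(th);
    for (int i = 0; i < nn; ++i) {
      if (is_skull[i]) {
        double rx = X[i] - cx, ry = Y[i] - cy;
        double nx = cx + ct * rx - st * ry + dx;
        double nyp = cy + st * rx + ct * ry + dy;
        vx[i] = (nx - X[i] - ux[i]) / dt;
        vy[i] = (nyp - Y[i] - uy[i]) / dt;
        ux[i] = nx - X[i]; uy[i] = nyp - Y[i];
      } else {
        double ax = -fx[i] / mass[i] - damping * vx[i];
        double ay = -fy[i] / mass[i] - damping * vy[i];
        vx[i] += ax * dt; vy[i] += ay * dt;
        ux[i] += vx[i] * dt; uy[i] += vy[i] * dt;
      }
    }

    t += dt;
    ++step;
    if (step % check_every == 0) {
      for (int i = 0; i < nn; ++i) {
        if (!std::isfinite(ux[i]) || !std::isfinite(uy[i]) ||
            std::fabs(ux[i]) > 20 * xmax || std::fabs(uy[i]) > 20 * xmax) {
          status = 1; t_fail = t; break;
        }
      }
      if (status) break;
      // re-estimate the stable step from current element geometry
      double dtmin = dt0;
      for (int e = 0; e < ne; ++e) {
        double xe[4], ye[4];
        for (int a = 0; a < 4; ++a) {
          int nd = elems(e, a) - 1;
          xe[a] = X[nd] + ux[nd]; ye[a] = Y[nd] + uy[nd];
        }
        double area = 0.5 * std::fabs(
          xe[0] * ye[1] - xe[1] * ye[0] + xe[1] * ye[2] - xe[2] * ye[1] +
          xe[2] * ye[3] - xe[3] * ye[2] + xe[3] * ye[0] - xe[0] * ye[3]);
        double emax = 0;
        for (int a = 0; a < 4; ++a) {
          int b = (a + 1) % 4;
          double el = std::sqrt((xe[b] - xe[a]) * (xe[b] - xe[a]) +
                                (ye[b] - ye[a]) * (ye[b] - ye[a]));
          if (el > emax) emax = el;
        }
        double dte = cfl_safety * (area / emax) / cwave[mid[e]];
        if (dte < dtmin) dtmin = dte;
      }
      dt = dtmin;
      if (step > max_steps) { status = 2; t_fail = t; break; }
    }
  }

  return List::create(_["peak_strain"] = NumericVector(peak_E.begin(), peak_E.end()),
                      _["peak_strain_rate"] = NumericVector(peak_R.begin(), peak_R.end()),
                      _["status"] = status, _["t_fail"] = t_fail);
}

// Point-in-element lookup on a quad mesh via background binning: returns the
// 1-based element containing each query point (0 where none). Quads are
// tested as two triangles with a small tolerance.
// [[Rcpp::export]]
IntegerVector cpp_locate_points(NumericMatrix nodes, IntegerMatrix elems,
                                NumericMatrix pts) {
  int ne = elems.nrow(), np = pts.nrow();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  std::vector<double> exmin(ne), exmax(ne), eymin(ne), eymax(ne);
  for (int e = 0; e < ne; ++e) {
    double a = R_PosInf, b = R_NegInf, c = R_PosInf, d = R_NegInf;
    for (int k = 0; k < 4; ++k) {
      int n = elems(e, k) - 1;
      double x = nodes(n, 0), y = nodes(n, 1);
      if (x < a) a = x; if (x > b) b = x;
      if (y < c) c = y; if (y > d) d = y;
    }
    exmin[e] = a; exmax[e] = b; eymin[e] = c; eymax[e] = d;
    if (a < xmin) xmin = a; if (b > xmax) xmax = b;
    if (c < ymin) ymin = c; if (d > ymax) ymax = d;
  }
  int nb = std::max(1, (int)std::sqrt((double)ne));
  double hx = (xmax - xmin) / nb, hy = (ymax - ymin) / nb;
  if (hx <= 0) hx = 1; if (hy <= 0) hy = 1;
  std::vector<std::vector<int>> bins((size_t)nb * nb);
  for (int e = 0; e < ne; ++e) {
    int i0 = std::min(nb - 1, std::max(0, (int)((exmin[e] - xmin) / hx)));
    int i1 = std::min(nb - 1, std::max(0, (int)((exmax[e] - xmin) / hx)));
    int j0 = std::min(nb - 1, std::max(0, (int)((eymin[e] - ymin) / hy)));
    int j1 = std::min(nb - 1, std::max(0, (int)((eymax[e] - ymin) / hy)));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)i * nb + j].push_back(e);
  }
  const double tol = -1e-12;
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1);
    out[p] = 0;
    if (px < xmin || px > xmax || py < ymin || py > ymax) continue;
    int bi = std::min(nb - 1, std::max(0, (int)((px - xmin) / hx)));
    int bj = std::min(nb - 1, std::max(0, (int)((py - ymin) / hy)));
    const std::vector<int> &cand = bins[(size_t)bi * nb + bj];
    for (size_t k = 0; k < cand.size(); ++k) {
      int e = cand[k];
      if (px < exmin[e] || px > exmax[e] || py < eymin[e] || py > eymax[e])
        continue;
      double xq[4], yq[4];
      for (int a = 0; a < 4; ++a) {
        int n = elems(e, a) - 1;
        xq[a] = nodes(n, 0); yq[a] = nodes(n, 1);
      }
      bool inside = false;
      int tris[2][3] = {{0, 1, 2}, {0, 2, 3}};
      for (int t = 0; t < 2 && !inside; ++t) {
        double x1 = xq[tris[t][0]], y1 = yq[tris[t][0]];
        double x2 = xq[tris[t][1]], y2 = yq[tris[t][1]];
        double x3 = xq[tris[t][2]], y3 = yq[tris[t][2]];
        double d1 = (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1);
        double d2 = (px - x2) * (y3 - y2) - (py - y2) * (x3 - x2);
        double d3 = (px - x3) * (y1 - y3) - (py - y3) * (x1 - x3);
        double scale = std::fabs((x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1));
        double lim = tol * scale;
        inside = (d1 >= lim && d2 >= lim && d3 >= lim) ||
                 (d1 <= -lim && d2 <= -lim && d3 <= -lim);
      }
      if (inside) { out[p] = e + 1; break; }
    }
  }
  return out;
}
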