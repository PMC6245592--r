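#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Steady lid-driven cavity in streamfunction-vorticity form, lid units
// (unit square, unit lid speed, nu = 1/Re). Explicit pseudo-time marching of
// the vorticity transport equation (first-order upwind convection, central
// diffusion) with a few SOR sweeps of the Poisson equation lap(psi) = -w per
// step and Thom wall-vorticity closures. Returns psi on the (n+1)x(n+1)
// nodes plus convergence diagnostics.
// [[Rcpp::export]]
List cavity_solve_cpp(int n, double Re, double tol, int max_iter,
                      double sor_beta, int n_sor) {
  const int m = n + 1;
  const double h = 1.0 / n;
  const double nu = 1.0 / Re;
  std::vector<double> psi(m * m, 0.0), w(m * m, 0.0), wn(m * m, 0.0);
  const double dt = 0.8 / (2.0 / h + 4.0 * nu / (h * h));
  const double h2 = h * h;
  double res = R_PosInf;
  int it = 0;
  auto ID = [m](int i, int j) { return i + m * j; }; // i: x-index, j: z-index
  for (it = 1; it <= max_iter; ++it) {
    // wall vorticity (Thom): psi = 0 on all walls; lid (j = n) moves with
    // unit velocity in +x
    for (int i = 0; i < m; ++i) {
      w[ID(i, 0)] = -2.0 * psi[ID(i, 1)] / h2;                 // bottom
      w[ID(i, n)] = -2.0 * psi[ID(i, n - 1)] / h2 - 2.0 / h;   // moving lid
    }
    for (int j = 0; j < m; ++j) {
      w[ID(0, j)] = -2.0 * psi[ID(1, j)] / h2;                 // left
      w[ID(n, j)] = -2.0 * psi[ID(n - 1, j)] / h2;             // right
    }
    // vorticity transport, explicit upwind step
    double maxrhs = 0.0;
    for (int j = 1; j < n; ++j) {
      for (int i = 1; i < n; ++i) {
        const double u = (psi[ID(i, j + 1)] - psi[ID(i, j - 1)]) / (2 * h);
        const double v = -(psi[ID(i + 1, j)] - psi[ID(i - 1, j)]) / (2 * h);
        const double wc = w[ID(i, j)];
        const double dwdx = (u > 0) ? (wc - w[ID(i - 1, j)]) / h
                                    : (w[ID(i + 1, j)] - wc) / h;
        const double dwdz = (v > 0) ? (wc - w[ID(i, j - 1)]) / h
                                    : (w[ID(i, j + 1)] - wc) / h;
        const double lap = (w[ID(i + 1, j)] + w[ID(i - 1, j)] +
                            w[ID(i, j + 1)] + w[ID(i, j - 1)] - 4.0 * wc) / h2;
        const double rhs = -u * dwdx - v * dwdz + nu * lap;
        wn[ID(i, j)] = wc + dt * rhs;
        const double a = std::fabs(rhs);
        if (a > maxrhs) maxrhs = a;
      }
    }
    for (int j = 1; j < n; ++j)
      for (int i = 1; i < n; ++i) w[ID(i, j)] = wn[ID(i, j)];
    // Poisson solve for psi: a few SOR sweeps (psi converges jointly with w)
    for (int s = 0; s < n_sor; ++s) {
      for (int j = 1; j < n; ++j) {
        for (int i = 1; i < n; ++i) {
          const double gs = 0.25 * (psi[ID(i + 1, j)] + psi[ID(i - 1, j)] +
                                    psi[ID(i, j + 1)] + psi[ID(i, j - 1)] +
                                    h2 * w[ID(i, j)]);
          psi[ID(i, j)] += sor_beta * (gs - psi[ID(i, j)]);
        }
      }
    }
    res = maxrhs; // steady-state residual: max |dw/dt|
    if (it > 50 && res < tol) break;
  }
  NumericMatrix psim(m, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i) psim(i, j) = psi[ID(i, j)];
  return List::create(_["psi"] = psim, _["iterations"] = it,
                      _["residual"] = res, _["converged"] = (res < tol));
}

// One explicit sub-step of conservative first-order upwind advection plus
// central diffusion with zero-flux (impermeable) walls, applied to the three
// species in a single pass. Face velocities are pre-split into positive and
// negative parts (uep/uem etc., flattened (nx+1) x nz and nx x (nz+1)), so
// the upwind selection is branch-free; wall faces carry zero velocity and
// contribute nothing. Fields stored column-major, i + nx*j.
static void advdiff_substep3(std::vector<double>* f[3],
                             std::vector<double>* fn[3],
                             const std::vector<double>& uep,
                             const std::vector<double>& uem,
                             const std::vector<double>& vnp,
                             const std::vector<double>& vnm,
                             int nx, int nz, double De,
                             double dx, double dz, double dts) {
  const double ax = dts / dx, az = dts / dz;
  const double kx = dts * De / (dx * dx), kz = dts * De / (dz * dz);
  for (int j = 0; j < nz; ++j) {
    const bool jlo = (j > 0), jhi = (j < nz - 1);
    for (int i = 0; i < nx; ++i) {
      const int id = i + nx * j;
      const bool ilo = (i > 0), ihi = (i < nx - 1);
      const double uepE = uep[(i + 1) + (nx + 1) * j], uemE = uem[(i + 1) + (nx + 1) * j];
      const double uepW = uep[i + (nx + 1) * j], uemW = uem[i + (nx + 1) * j];
      const double vnpN = vnp[i + nx * (j + 1)], vnmN = vnm[i + nx * (j + 1)];
      const double vnpS = vnp[i + nx * j], vnmS = vnm[i + nx * j];
      for (int s = 0; s < 3; ++s) {
        const std::vector<double>& c = *f[s];
        const double cc = c[id];
        const double cE = ihi ? c[id + 1] : cc;
        const double cW = ilo ? c[id - 1] : cc;
        const double cN = jhi ? c[id + nx] : cc;
        const double cS = jlo ? c[id - nx] : cc;
        const double fe = uepE * cc + uemE * cE;
        const double fw = uepW * cW + uemW * cc;
        const double fnl = vnpN * cc + vnmN * cN;
        const double fs = vnpS * cS + vnmS * cc;
        double out = cc - ax * (fe - fw) - az * (fnl - fs);
        out += kx * (cE - 2.0 * cc + cW) + kz * (cN - 2.0 * cc + cS);
        (*fn[s])[id] = out;
      }
    }
  }
  for (int s = 0; s < 3; ++s) f[s]->swap(*fn[s]);
}

static inline double minmod(double a, double b) {
  if (a > 0 && b > 0) return a < b ? a : b;
  if (a < 0 && b < 0) return a > b ? a : b;
  return 0.0;
}

// Second-order MUSCL variant: face states reconstructed from minmod-limited
// slopes (reverting to first order at wall-adjacent faces), same diffusion
// and boundary treatment. TVD under a stricter CFL bound, enforced by the
// caller via a smaller sub-step target.
static void advdiff_substep3_muscl(std::vector<double>* f[3],
                                   std::vector<double>* fn[3],
                                   std::vector<double>& sx,
                                   std::vector<double>& sz,
                                   const std::vector<double>& uep,
                                   const std::vector<double>& uem,
                                   const std::vector<double>& vnp,
                                   const std::vector<double>& vnm,
                                   int nx, int nz, double De,
                                   double dx, double dz, double dts) {
  const double ax = dts / dx, az = dts / dz;
  const double kx = dts * De / (dx * dx), kz = dts * De / (dz * dz);
  for (int s = 0; s < 3; ++s) {
    const std::vector<double>& c = *f[s];
    for (int j = 0; j < nz; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int id = i + nx * j;
        sx[id] = (i > 0 && i < nx - 1)
          ? minmod(c[id] - c[id - 1], c[id + 1] - c[id]) : 0.0;
        sz[id] = (j > 0 && j < nz - 1)
          ? minmod(c[id] - c[id - nx], c[id + nx] - c[id]) : 0.0;
      }
    }
    for (int j = 0; j < nz; ++j) {
      const bool jlo = (j > 0), jhi = (j < nz - 1);
      for (int i = 0; i < nx; ++i) {
        const int id = i + nx * j;
        const bool ilo = (i > 0), ihi = (i < nx - 1);
        const double cc = c[id];
        const double cE = ihi ? c[id + 1] : cc;
        const double cW = ilo ? c[id - 1] : cc;
        const double cN = jhi ? c[id + nx] : cc;
        const double cS = jlo ? c[id - nx] : cc;
        double fe = 0.0, fw = 0.0, fnl = 0.0, fs = 0.0;
        if (ihi) {
          fe = uep[(i + 1) + (nx + 1) * j] * (cc + 0.5 * sx[id]) +
               uem[(i + 1) + (nx + 1) * j] * (cE - 0.5 * sx[id + 1]);
        }
        if (ilo) {
          fw = uep[i + (nx + 1) * j] * (cW + 0.5 * sx[id - 1]) +
               uem[i + (nx + 1) * j] * (cc - 0.5 * sx[id]);
        }
        if (jhi) {
          fnl = vnp[i + nx * (j + 1)] * (cc + 0.5 * sz[id]) +
                vnm[i + nx * (j + 1)] * (cN - 0.5 * sz[id + nx]);
        }
        if (jlo) {
          fs = vnp[i + nx * j] * (cS + 0.5 * sz[id - nx]) +
               vnm[i + nx * j] * (cc - 0.5 * sz[id]);
        }
        double out = cc - ax * (fe - fw) - az * (fnl - fs);
        out += kx * (cE - 2.0 * cc + cW) + kz * (cN - 2.0 * cc + cS);
        (*fn[s])[id] = out;
      }
    }
  }
  for (int s = 0; s < 3; ++s) f[s]->swap(*fn[s]);
}

static inline void homogenize(std::vector<double>& c, int ncell) {
  double s = 0.0;
  for (int k = 0; k < ncell; ++k) s += c[k];
  s /= ncell;
  for (int k = 0; k < ncell; ++k) c[k] = s;
}

// Operator-split transport-reaction time stepper for the three PSF species
// fractions on a frozen velocity field.
//   mixing_mode: 0 advect+diffuse (sub-cycled explicit), 1 ideal mixing
//     (exact spatial homogenization, the De -> infinity limit), 2 none.
//   react_mode: 0 off; 1 full (per-level 3x3 exact propagators 'prop',
//     9 x nz, column-major per z-level); 2 reduced (yA relaxation with
//     decay factor edk = exp(-k(z) dt) and fixed point fp(z); yB frozen).
// Records domain means every rec_stride macro steps.
// [[Rcpp::export]]
List transport_run_cpp(NumericMatrix yR0, NumericMatrix yA0, NumericMatrix yB0,
                       NumericMatrix ue, NumericMatrix vn,
                       double De, double dx, double dz, double dt,
                       int nsteps, int nsub, int mixing_mode, int react_mode,
                       NumericMatrix prop, NumericVector edk, NumericVector fp,
                       double yB_frozen, int rec_stride, double t0,
                       int adv_order) {
  const int nx = yR0.nrow(), nz = yR0.ncol(), ncell = nx * nz;
  std::vector<double> yR(ncell), yA(ncell), yB(ncell);
  std::vector<double> tR(ncell), tA(ncell), tB(ncell);
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nx; ++i) {
      yR[i + nx * j] = yR0(i, j);
      yA[i + nx * j] = yA0(i, j);
      yB[i + nx * j] = yB0(i, j);
    }
  std::vector<double>* fld[3] = {&yR, &yA, &yB};
  std::vector<double>* flt[3] = {&tR, &tA, &tB};
  // upwind-split face velocities (positive / negative parts)
  std::vector<double> uep((nx + 1) * nz), uem((nx + 1) * nz);
  std::vector<double> vnp(nx * (nz + 1)), vnm(nx * (nz + 1));
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i <= nx; ++i) {
      const double v = ue(i, j);
      uep[i + (nx + 1) * j] = v > 0 ? v : 0.0;
      uem[i + (nx + 1) * j] = v < 0 ? v : 0.0;
    }
  for (int j = 0; j <= nz; ++j)
    for (int i = 0; i < nx; ++i) {
      const double v = vn(i, j);
      vnp[i + nx * j] = v > 0 ? v : 0.0;
      vnm[i + nx * j] = v < 0 ? v : 0.0;
    }
  std::vector<double> slx(ncell), slz(ncell);
  const double dts = dt / nsub;
  const int nrec = nsteps / rec_stride + 1;
  NumericMatrix traj(nrec, 4);
  int irec = 0;
  auto record = [&](double t) {
    double sR = 0, sA = 0, sB = 0;
    for (int k = 0; k < ncell; ++k) { sR += yR[k]; sA += yA[k]; sB += yB[k]; }
    traj(irec, 0) = t;
    traj(irec, 1) = sR / ncell;
    traj(irec, 2) = sA / ncell;
    traj(irec, 3) = sB / ncell;
    ++irec;
  };
  record(t0);
  for (int step = 1; step <= nsteps; ++step) {
    if (mixing_mode == 0) {
      for (int s = 0; s < nsub; ++s) {
        if (adv_order == 2) {
          advdiff_substep3_muscl(fld, flt, slx, slz, uep, uem, vnp, vnm,
                                 nx, nz, De, dx, dz, dts);
        } else {
          advdiff_substep3(fld, flt, uep, uem, vnp, vnm, nx, nz, De, dx, dz, dts);
        }
      }
    } else if (mixing_mode == 1) {
      homogenize(yR, ncell);
      homogenize(yA, ncell);
      homogenize(yB, ncell);
    }
    if (react_mode == 1) {
      for (int j = 0; j < nz; ++j) {
        const double p11 = prop(0, j), p21 = prop(1, j), p31 = prop(2, j);
        const double p12 = prop(3, j), p22 = prop(4, j), p32 = prop(5, j);
        const double p13 = prop(6, j), p23 = prop(7, j), p33 = prop(8, j);
        for (int i = 0; i < nx; ++i) {
          const int id = i + nx * j;
          const double r = yR[id], a = yA[id], b = yB[id];
          yR[id] = p11 * r + p12 * a + p13 * b;
          yA[id] = p21 * r + p22 * a + p23 * b;
          yB[id] = p31 * r + p32 * a + p33 * b;
        }
      }
    } else if (react_mode == 2) {
      for (int j = 0; j < nz; ++j) {
        const double e = edk[j], f = fp[j];
        for (int i = 0; i < nx; ++i) {
          const int id = i + nx * j;
          const double a = f + (yA[id] - f) * e;
          yA[id] = a;
          yB[id] = yB_frozen;
          yR[id] = 1.0 - a - yB_frozen;
        }
      }
    }
    if (step % rec_stride == 0 && irec < nrec) record(t0 + step * dt);
    if (step % 2000 == 0) {
      // blow-up guard
      for (int k = 0; k < ncell; k += 97) {
        if (!std::isfinite(yA[k])) {
          stop("transport_run_cpp: non-finite field detected at t = %f",
               t0 + step * dt);
        }
      }
    }
  }
  NumericMatrix oR(nx, nz), oA(nx, nz), oB(nx, nz);
  double lo = 1.0, hi = 0.0;
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nx; ++i) {
      const int id = i + nx * j;
      oR(i, j) = yR[id]; oA(i, j) = yA[id]; oB(i, j) = yB[id];
      for (const double v : {yR[id], yA[id], yB[id]}) {
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
    }
  return List::create(_["yR"] = oR, _["yA"] = oA, _["yB"] = oB,
                      _["traj"] = traj(Range(0, irec - 1), _),
                      _["min_fraction"] = lo, _["max_fraction"] = hi);
}
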