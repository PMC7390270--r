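#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Finite-volume stepper for the 2D channel model: upwind advection,
// central diffusion, pointwise kinetics, saturating platelet transport and
// the tissue-factor surface reaction. Cell-centered fields on an nx x ny
// grid (x along the channel, y across; the injured wall is the bottom row
// j = 0). Face velocities come from the quasi-steady Stokes-Brinkman solve
// done on the R side. All transport is in flux form, so closed-box totals
// are conserved to round-off.

struct Grid {
  int nx, ny;
  double h;
};

// inlet boundary treatment per species
enum InletBC { INLET_DIRICHLET, INLET_CLEAN };  // CLEAN: inflowing plasma carries zero

static inline double dav_resistance(double Fp, double phic, double inv_a2_16,
                                    double Fp_ref, double Fp_cap,
                                    double phimax) {
  double Ft = Fp / Fp_ref;
  if (Ft > Fp_cap) Ft = Fp_cap;
  if (Ft <= 0.0) return 0.0;
  double dens = (phimax - phic);
  if (dens < 1e-12) dens = 1e-12;
  return inv_a2_16 * std::pow(Ft, 1.5) * (1.0 + 56.0 * Ft * Ft * Ft) *
         (phimax + phic) / dens;
}

// advect-diffuse one scalar field (no mobility weighting)
static void transport_scalar(const std::vector<double>& C,
                             std::vector<double>& Cn,
                             const double* u, const double* v,
                             const Grid& g, double D, double dt,
                             InletBC bc, double Cin, bool closed) {
  const int nx = g.nx, ny = g.ny;
  const double h = g.h;
  // x-direction fluxes per row, then y-direction; accumulate divergence
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) Cn[i + nx * j] = C[i + nx * j];
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i <= nx; ++i) {
      double flux = 0.0;
      if (closed && (i == 0 || i == nx)) {
        flux = 0.0;
      } else if (i == 0) {
        double uu = u[0 + (nx + 1) * j];
        if (bc == INLET_DIRICHLET) {
          double adv = uu > 0 ? uu * Cin : uu * C[0 + nx * j];
          double dif = -D * (C[0 + nx * j] - Cin) / (h / 2.0);
          flux = adv + dif;
        } else {
          flux = uu > 0 ? 0.0 : uu * C[0 + nx * j];
        }
      } else if (i == nx) {
        double uu = u[nx + (nx + 1) * j];
        flux = uu > 0 ? uu * C[(nx - 1) + nx * j] : 0.0;
      } else {
        double uu = u[i + (nx + 1) * j];
        double up = uu > 0 ? C[(i - 1) + nx * j] : C[i + nx * j];
        flux = uu * up - D * (C[i + nx * j] - C[(i - 1) + nx * j]) / h;
      }
      if (i > 0) Cn[(i - 1) + nx * j] -= dt / h * flux;
      if (i < nx) Cn[i + nx * j] += dt / h * flux;
    }
  }
  for (int i = 0; i < nx; ++i) {
    for (int j = 1; j < ny; ++j) {  // interior horizontal faces only (walls: zero flux)
      double vv = v[i + nx * j];
      double up = vv > 0 ? C[i + nx * (j - 1)] : C[i + nx * j];
      double flux = vv * up - D * (C[i + nx * j] - C[i + nx * (j - 1)]) / h;
      Cn[i + nx * (j - 1)] -= dt / h * flux;
      Cn[i + nx * j] += dt / h * flux;
    }
  }
}

// joint transport of both platelet classes. Every face flux carries the
// traffic-flow mobility k(phi_tot) evaluated at the larger of the two
// adjacent total densities (so flux into a saturated cell vanishes), and a
// one-pass limiter scales down incoming fluxes that would push a cell's
// total past phi_max. The limiter scales donor and receiver symmetrically,
// so closed-box totals remain conserved to round-off.
static void transport_platelets(std::vector<double>& phif,
                                std::vector<double>& phic,
                                std::vector<double>& bf,
                                std::vector<double>& bc,
                                const double* u, const double* v,
                                const Grid& g, double Dp, double phimax,
                                double dt, double phif_in, bool closed) {
  const int nx = g.nx, ny = g.ny;
  const double h = g.h;
  const double pi = 3.14159265358979323846;
  const int nfx = (nx + 1) * ny, nfy = nx * (ny + 1);
  static std::vector<double> Ffx, Fcx, Ffy, Fcy, phitot, incoming, scale;
  Ffx.assign(nfx, 0.0); Fcx.assign(nfx, 0.0);
  Ffy.assign(nfy, 0.0); Fcy.assign(nfy, 0.0);
  phitot.resize(nx * ny); incoming.assign(nx * ny, 0.0);
  scale.assign(nx * ny, 1.0);
  for (int id = 0; id < nx * ny; ++id) phitot[id] = phif[id] + phic[id];
  auto mob = [&](double pt) {
    double arg = pi * (1.0 - pt / phimax);
    if (arg <= 0.0) return 0.0;
    return std::tanh(arg);
  };
  // x faces
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i <= nx; ++i) {
      int fid = i + (nx + 1) * j;
      if (closed && (i == 0 || i == nx)) continue;
      if (i == 0) {
        double uu = u[fid];
        double k = mob(phitot[0 + nx * j]);
        if (uu > 0) {
          Ffx[fid] = k * (uu * phif_in -
                          Dp * (phif[0 + nx * j] - phif_in) / (h / 2.0));
          Fcx[fid] = 0.0;  // no clot platelets upstream
        } else {
          Ffx[fid] = k * uu * phif[0 + nx * j];
          Fcx[fid] = k * uu * phic[0 + nx * j];
        }
      } else if (i == nx) {
        double uu = u[fid];
        double k = mob(phitot[(nx - 1) + nx * j]);
        if (uu > 0) {
          Ffx[fid] = k * uu * phif[(nx - 1) + nx * j];
          Fcx[fid] = k * uu * phic[(nx - 1) + nx * j];
        }
      } else {
        double uu = u[fid];
        int l = (i - 1) + nx * j, r = i + nx * j;
        double k = mob(std::max(phitot[l], phitot[r]));
        double upf = uu > 0 ? phif[l] : phif[r];
        double upc = uu > 0 ? phic[l] : phic[r];
        Ffx[fid] = k * (uu * upf - Dp * (phif[r] - phif[l]) / h);
        Fcx[fid] = k * (uu * upc - Dp * (phic[r] - phic[l]) / h);
      }
    }
  }
  // interior y faces (walls have zero flux)
  for (int i = 0; i < nx; ++i) {
    for (int j = 1; j < ny; ++j) {
      int fid = i + nx * j;
      double vv = v[fid];
      int b = i + nx * (j - 1), t = i + nx * j;
      double k = mob(std::max(phitot[b], phitot[t]));
      double upf = vv > 0 ? phif[b] : phif[t];
      double upc = vv > 0 ? phic[b] : phic[t];
      Ffy[fid] = k * (vv * upf - Dp * (phif[t] - phif[b]) / h);
      Fcy[fid] = k * (vv * upc - Dp * (phic[t] - phic[b]) / h);
    }
  }
  // limiter: cap incoming platelet mass so no cell's total exceeds
  // phi_max. Each species flux is tallied against the cell it flows into
  // (phi_f and phi_c through the same face may flow in opposite
  // directions) and scaled by that receiver's admittance.
  auto recv_x = [&](int i, int j, double Fl) {
    if (Fl > 0) return i < nx ? i + nx * j : -1;
    if (Fl < 0) return i > 0 ? (i - 1) + nx * j : -1;
    return -1;
  };
  auto recv_y = [&](int i, int j, double Fl) {
    if (Fl > 0) return i + nx * j;
    if (Fl < 0) return i + nx * (j - 1);
    return -1;
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int fid = i + (nx + 1) * j;
      int rf = recv_x(i, j, Ffx[fid]);
      int rc = recv_x(i, j, Fcx[fid]);
      if (rf >= 0) incoming[rf] += std::abs(Ffx[fid]) * dt / h;
      if (rc >= 0) incoming[rc] += std::abs(Fcx[fid]) * dt / h;
    }
  for (int i = 0; i < nx; ++i)
    for (int j = 1; j < ny; ++j) {
      int fid = i + nx * j;
      int rf = recv_y(i, j, Ffy[fid]);
      int rc = recv_y(i, j, Fcy[fid]);
      if (rf >= 0) incoming[rf] += std::abs(Ffy[fid]) * dt / h;
      if (rc >= 0) incoming[rc] += std::abs(Fcy[fid]) * dt / h;
    }
  for (int id = 0; id < nx * ny; ++id) {
    double room = phimax - phitot[id];
    if (room < 0.0) room = 0.0;
    if (incoming[id] > room && incoming[id] > 0.0)
      scale[id] = room / incoming[id];
  }
  auto sc_of = [&](int rec) { return rec >= 0 ? scale[rec] : 1.0; };
  // divergence update
  for (int id = 0; id < nx * ny; ++id) { bf[id] = phif[id]; bc[id] = phic[id]; }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int fid = i + (nx + 1) * j;
      double ff = sc_of(recv_x(i, j, Ffx[fid])) * Ffx[fid];
      double fc = sc_of(recv_x(i, j, Fcx[fid])) * Fcx[fid];
      if (i > 0) { bf[(i - 1) + nx * j] -= dt / h * ff; bc[(i - 1) + nx * j] -= dt / h * fc; }
      if (i < nx) { bf[i + nx * j] += dt / h * ff; bc[i + nx * j] += dt / h * fc; }
    }
  for (int i = 0; i < nx; ++i)
    for (int j = 1; j < ny; ++j) {
      int fid = i + nx * j;
      double ff = sc_of(recv_y(i, j, Ffy[fid])) * Ffy[fid];
      double fc = sc_of(recv_y(i, j, Fcy[fid])) * Fcy[fid];
      bf[i + nx * (j - 1)] -= dt / h * ff; bc[i + nx * (j - 1)] -= dt / h * fc;
      bf[i + nx * j] += dt / h * ff; bc[i + nx * j] += dt / h * fc;
    }
  phif.swap(bf); phic.swap(bc);
}

// implicit update of a patch cell's Ba from the saturating Robin influx
// D dBa/dn = alpha1 (B0 - Ba) / (1 + beta1 (B0 - Ba));
// backward-Euler in the cell balance gives a quadratic for x = B0 - Ba_new
static inline double robin_update(double Ba, double dt_over_h, double alpha1,
                                  double beta1, double B0) {
  double g = B0 - Ba;
  if (g <= 0.0) return Ba;
  double c = dt_over_h * alpha1;
  double b = 1.0 + c - g * beta1;
  double x = (-b + std::sqrt(b * b + 4.0 * beta1 * g)) / (2.0 * beta1);
  if (x < 0.0) x = 0.0;
  if (x > g) x = g;
  return B0 - x;
}

// [[Rcpp::export]]
List step_species_cpp(List fields, NumericMatrix u, NumericMatrix v,
                      List grid, List pars, double dt, int nsteps,
                      double t0, int rec_stride,
                      IntegerVector patch_cols, IntegerVector near_cols,
                      bool closed) {
  Grid g;
  g.nx = as<int>(grid["nx"]);
  g.ny = as<int>(grid["ny"]);
  g.h = as<double>(grid["h"]);
  const int nx = g.nx, ny = g.ny, ncell = nx * ny;

  auto getf = [&](const char* nm) {
    NumericMatrix m = as<NumericMatrix>(fields[nm]);
    if (m.nrow() != nx || m.ncol() != ny) stop("field dimension mismatch");
    return std::vector<double>(m.begin(), m.end());
  };
  std::vector<double> P = getf("P"), T = getf("T"), Ba = getf("Ba"),
    A = getf("A"), Fg = getf("Fg"), F = getf("F"), Fp = getf("Fp"),
    phif = getf("phif"), phic = getf("phic");
  std::vector<double> buf(ncell), buf2(ncell);

  const double k1 = pars["k1"], k2 = pars["k2"], k3 = pars["k3"],
    k4 = pars["k4"], k5 = pars["k5"], k6 = pars["k6"], k7 = pars["k7"],
    k8 = pars["k8"], k9 = pars["k9"], k10 = pars["k10"], K10 = pars["K10"],
    k11 = pars["k11"], k12 = pars["k12"], k13 = pars["k13"],
    D = pars["D"], Dp = pars["Dp"], phimax = pars["phi_max"],
    B0 = pars["B0"], P0 = pars["P0"], A0 = pars["A0"], Fg0 = pars["Fg0"],
    phif0 = pars["phi_f0"], phic0 = pars["phi_c0"],
    alpha1 = pars["alpha1"], beta1 = pars["beta1"],
    alpha_fib = pars["alpha"], Fp_ref = pars["Fp_ref"],
    Fp_cap = pars["Fp_cap"];
  const double inv_a2_16 = 16.0 / (alpha_fib * alpha_fib);
  const bool react = as<bool>(pars["react"]);

  const double* pu = u.begin();
  const double* pv = v.begin();
  if (u.nrow() != nx + 1 || u.ncol() != ny) stop("u dimension mismatch");
  if (v.nrow() != nx || v.ncol() != ny + 1) stop("v dimension mismatch");

  int nrec = (rec_stride > 0) ? (nsteps / rec_stride + 1) : 0;
  NumericMatrix timeline(nrec, 4);  // t, maxFp_near, maxInvKf_near, maxT
  int irec = 0;
  double minval = 0.0;

  auto record = [&](double t) {
    if (irec >= nrec) return;
    double mFp = 0.0, mR = 0.0, mT = 0.0;
    for (int jj = 0; jj < ny; ++jj)
      for (int kk = 0; kk < near_cols.size(); ++kk) {
        int i = near_cols[kk];
        int id = i + nx * jj;
        if (Fp[id] > mFp) mFp = Fp[id];
        double r = dav_resistance(Fp[id], phic[id], inv_a2_16, Fp_ref,
                                  Fp_cap, phimax);
        if (r > mR) mR = r;
      }
    for (int id = 0; id < ncell; ++id) if (T[id] > mT) mT = T[id];
    timeline(irec, 0) = t;
    timeline(irec, 1) = mFp;
    timeline(irec, 2) = mR;
    timeline(irec, 3) = mT;
    ++irec;
  };

  for (int step = 0; step < nsteps; ++step) {
    if (rec_stride > 0 && step % rec_stride == 0) record(t0 + step * dt);
    // --- transport ---
    transport_scalar(P, buf, pu, pv, g, D, dt, INLET_DIRICHLET, P0, closed); P.swap(buf);
    transport_scalar(T, buf, pu, pv, g, D, dt, INLET_CLEAN, 0.0, closed); T.swap(buf);
    transport_scalar(Ba, buf, pu, pv, g, D, dt, INLET_CLEAN, 0.0, closed); Ba.swap(buf);
    transport_scalar(A, buf, pu, pv, g, D, dt, INLET_DIRICHLET, A0, closed); A.swap(buf);
    transport_scalar(Fg, buf, pu, pv, g, D, dt, INLET_DIRICHLET, Fg0, closed); Fg.swap(buf);
    transport_scalar(F, buf, pu, pv, g, D, dt, INLET_CLEAN, 0.0, closed); F.swap(buf);
    // fibrin polymer is immobile; platelets move jointly with the
    // saturation limiter
    transport_platelets(phif, phic, buf, buf2, pu, pv, g, Dp, phimax, dt,
                        phif0, closed);

    // --- surface reaction on the TF patch (bottom wall, j = 0) ---
    if (react) {
      for (int kk = 0; kk < patch_cols.size(); ++kk) {
        int i = patch_cols[kk];
        Ba[i + nx * 0] = robin_update(Ba[i + nx * 0], dt / g.h, alpha1,
                                      beta1, B0);
        if (phic[i + nx * 0] < phic0) phic[i + nx * 0] = phic0;
      }
    }

    // --- kinetics (pairwise-conservative exponential updates) ---
    if (react) {
      for (int id = 0; id < ncell; ++id) {
        double Tc = T[id], Pc = P[id], Bac = Ba[id], Ac = A[id];
        // prothrombin -> thrombin
        double R1 = k1 * phic[id] + k2 * Bac + k3 * Tc + k4 * Tc * Tc +
          k5 * Tc * Tc * Tc;
        double Pn = Pc * std::exp(-R1 * dt);
        double dT = Pc - Pn;
        // thrombin and IXa/Xa neutralization by antithrombin
        double inhT = k6 * Ac * dt;
        double inhB = k9 * Ac * dt;
        double Tn = (Tc + dT) * std::exp(-inhT);
        // IXa/Xa activation by platelets and thrombin, saturating at B0
        double actB = (k7 * phic[id] + k8 * Tc) * dt;
        double Ban = Bac + (B0 - Bac) * (1.0 - std::exp(-actB));
        Ban *= std::exp(-inhB);
        // antithrombin consumption
        double An = Ac - (k6 * Tc + k9 * Bac) * Ac * dt;
        if (An < 0.0) An = 0.0;
        // fibrinogen -> fibrin -> polymer
        double conv_rate = k10 * Tc / (K10 + Fg[id]);
        double Fgn = Fg[id] * std::exp(-conv_rate * dt);
        double dF = Fg[id] - Fgn;
        double Fn = (F[id] + dF) * std::exp(-k11 * dt);
        double dFp = (F[id] + dF) * (1.0 - std::exp(-k11 * dt));
        // platelet activation
        double act = (k12 * Tc + k13 * phic[id]) * dt;
        double phifn = phif[id] * std::exp(-act);
        double dphic = phif[id] - phifn;
        P[id] = Pn; T[id] = Tn; Ba[id] = Ban; A[id] = An;
        Fg[id] = Fgn; F[id] = Fn; Fp[id] += dFp;
        phif[id] = phifn; phic[id] += dphic;
      }
    }
    for (int id = 0; id < ncell; ++id) {
      double worst = P[id];
      if (T[id] < worst) worst = T[id];
      if (Ba[id] < worst) worst = Ba[id];
      if (A[id] < worst) worst = A[id];
      if (phif[id] < worst) worst = phif[id];
      if (phic[id] < worst) worst = phic[id];
      if (worst < minval) minval = worst;
    }
  }
  if (rec_stride > 0) record(t0 + nsteps * dt);

  auto out = [&](std::vector<double>& val) {
    NumericMatrix m(nx, ny);
    std::copy(val.begin(), val.end(), m.begin());
    return m;
  };
  return List::create(
    _["P"] = out(P), _["T"] = out(T), _["Ba"] = out(Ba), _["A"] = out(A),
    _["Fg"] = out(Fg), _["F"] = out(F), _["Fp"] = out(Fp),
    _["phif"] = out(phif), _["phic"] = out(phic),
    _["timeline"] = timeline, _["min_value"] = minval,
    _["t_end"] = t0 + nsteps * dt);
}
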