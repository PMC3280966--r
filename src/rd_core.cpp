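// Structured-grid core for the FGF10/SHH/Ptc reaction-diffusion model.
//
// Space: cell-centred Cartesian grid, x physical, axial coordinate mapped to
// xi = y/L(t) in [0,1] so that 1-D axial growth keeps the computational grid
// fixed. Time stepping is first-order operator splitting:
//   (1) explicit conservative upwind advection + dilution (growing domains),
//   (2) pointwise implicit (backward-Euler) kinetics solved by damped Newton,
//   (3) implicit axis-by-axis diffusion solved with the Thomas algorithm.
// Diffusion is an M-matrix and the kinetics step clamps at zero, so fields
// stay non-negative.
//
// Subdomain labels: 1 lumen, 2 epithelium, 3 mesenchyme, 4 interstitium/buffer.
// Parameter columns (per-label table and optional per-cell multipliers):
//   0 Df, 1 Ds, 2 Dp, 3 nu_f, 4 nu_s, 5 rho0, 6 rho1,
//   7 delta_f, 8 delta_s, 9 delta_p, 10 delta_c, 11 gamma, 12 Kf, 13 Ks
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NPAR = 14;

struct Geom {
  double rc, we, Rc;        // lumen radius, epithelial thickness, mesenchyme radius
  double se, sm;            // tip epithelial / mesenchymal radius scale factors
  double wb;                // axial blend width for tip deformations
  double cap_off;           // L = h_stalk + cap_off (outer cap + top buffer)
};

static Geom geom_from_list(const List& g) {
  Geom gm;
  gm.rc = as<double>(g["rc"]);
  gm.we = as<double>(g["we"]);
  gm.Rc = as<double>(g["Rc"]);
  gm.se = as<double>(g["tip_epithelium_scale"]);
  gm.sm = as<double>(g["tip_mesenchyme_scale"]);
  gm.wb = as<double>(g["blend_width"]);
  gm.cap_off = as<double>(g["cap_off"]);
  return gm;
}

static inline double smoothstep01(double t) {
  if (t <= 0.0) return 0.0;
  if (t >= 1.0) return 1.0;
  return t * t * (3.0 - 2.0 * t);
}

// Subdomain label at a physical point, for stalk length h.
static inline int point_label(double x, double y, double h, const Geom& g) {
  double blend = (g.wb > 0.0) ? smoothstep01((y - (h - g.wb)) / g.wb)
                              : (y >= h ? 1.0 : 0.0);
  double se = 1.0 + (g.se - 1.0) * blend;
  double sm = 1.0 + (g.sm - 1.0) * blend;
  double rho = (y <= h) ? std::fabs(x) : std::hypot(x, y - h);
  if (rho < g.rc * se) return 1;
  if (rho < (g.rc + g.we) * se) return 2;
  if (rho < g.Rc * sm) return 3;
  return 4;
}

// [[Rcpp::export]]
IntegerMatrix rd_labels(NumericVector x, NumericVector y, double h_stalk, List geom) {
  Geom g = geom_from_list(geom);
  int nx = x.size(), ny = y.size();
  IntegerMatrix lab(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      lab(i, j) = point_label(x[i], y[j], h_stalk, g);
  return lab;
}

// ---------------------------------------------------------------------------
// kinetics

struct Kin {
  int n, nS, mP;
  bool full;                // explicit complex field instead of QSSA
  double kon, koff;
};

static inline double ipow(double b, int e) {
  double r = 1.0;
  for (int i = 0; i < e; ++i) r *= b;
  return r;
}

// Backward-Euler step of the reaction terms at one cell.
// z = (f, s, p); par = pointer to the 14 per-cell parameters.
// In full mode c0 is the complex concentration; its backward-Euler update
// c_new = (c0 + dt kon S P) / (1 + dt (koff + delta_c)) is eliminated into
// the z-equations and written back on convergence.
static bool newton_cell(double* z, const double* par, double dt, const Kin& kin,
                        double* c0) {
  const double nu_f = par[3], nu_s = par[4], rho0 = par[5], rho1 = par[6];
  const double d_f = par[7], d_s = par[8], d_p = par[9], d_c = par[10];
  const double gam = par[11], Kf = par[12], Ks = par[13];
  const double Kfn = ipow(Kf, kin.n), Ksn = ipow(Ks, kin.n);
  const double z0[3] = { z[0], z[1], z[2] };
  const double B = kin.full ? 1.0 / (1.0 + dt * (kin.koff + d_c)) : 0.0;

  for (int it = 0; it < 50; ++it) {
    double f = z[0], s = z[1], p = z[2];
    double S = ipow(s, kin.nS), P = ipow(p, kin.mP);
    double dS = kin.nS > 0 ? kin.nS * ipow(s, kin.nS - 1) : 0.0;
    double dP = kin.mP > 0 ? kin.mP * ipow(p, kin.mP - 1) : 0.0;
    double c, dc_ds, dc_dp, sink_s, dss_ds, dss_dp;
    if (!kin.full) {
      c = gam * S * P;
      dc_ds = gam * dS * P;
      dc_dp = gam * S * dP;
      sink_s = d_c * c;            // net complex-mediated removal of s
      dss_ds = d_c * dc_ds;
      dss_dp = d_c * dc_dp;
    } else {
      c = B * (*c0 + dt * kin.kon * S * P);
      dc_ds = B * dt * kin.kon * dS * P;
      dc_dp = B * dt * kin.kon * S * dP;
      sink_s = kin.kon * S * P - kin.koff * c;
      dss_ds = kin.kon * dS * P - kin.koff * dc_ds;
      dss_dp = kin.kon * S * dP - kin.koff * dc_dp;
    }
    double cn = ipow(c, kin.n);
    double rep = (nu_f > 0.0) ? Kfn / (Kfn + cn) : 0.0;
    double drep = (nu_f > 0.0 && c > 0.0)
                    ? -kin.n * ipow(c, kin.n - 1) * Kfn / ((Kfn + cn) * (Kfn + cn))
                    : 0.0;
    double fn = ipow(f, kin.n);
    double H = fn / (Ksn + fn);
    double dH = (f > 0.0) ? kin.n * ipow(f, kin.n - 1) * Ksn / ((Ksn + fn) * (Ksn + fn))
                          : (kin.n == 1 ? 1.0 / Ksn : 0.0);

    double R[3] = {
      nu_f * rep - d_f * f,
      nu_s * H - d_s * s - sink_s,
      rho0 + rho1 * c - d_p * p - kin.mP * sink_s
    };
    double g0 = z[0] - z0[0] - dt * R[0];
    double g1 = z[1] - z0[1] - dt * R[1];
    double g2 = z[2] - z0[2] - dt * R[2];
    double scale = 1.0 + std::fabs(z[0]) + std::fabs(z[1]) + std::fabs(z[2]);
    if (std::fabs(g0) + std::fabs(g1) + std::fabs(g2) < 1e-12 * scale) {
      if (kin.full) *c0 = c;
      return true;
    }
    // J = I - dt * dR/dz
    double a00 = 1.0 - dt * (-d_f);
    double a01 = -dt * (nu_f * drep * dc_ds);
    double a02 = -dt * (nu_f * drep * dc_dp);
    double a10 = -dt * (nu_s * dH);
    double a11 = 1.0 - dt * (-d_s - dss_ds);
    double a12 = -dt * (-dss_dp);
    double a20 = 0.0;
    double a21 = -dt * (rho1 * dc_ds - kin.mP * dss_ds);
    double a22 = 1.0 - dt * (rho1 * dc_dp - kin.mP * dss_dp - d_p);
    double det = a00 * (a11 * a22 - a12 * a21) - a01 * (a10 * a22 - a12 * a20)
               + a02 * (a10 * a21 - a11 * a20);
    if (det == 0.0 || !std::isfinite(det)) return false;
    double d0 = (-g0) * (a11 * a22 - a12 * a21) - a01 * ((-g1) * a22 - a12 * (-g2))
              + a02 * ((-g1) * a21 - a11 * (-g2));
    double d1 = a00 * ((-g1) * a22 - a12 * (-g2)) - (-g0) * (a10 * a22 - a12 * a20)
              + a02 * (a10 * (-g2) - (-g1) * a20);
    double d2 = a00 * (a11 * (-g2) - (-g1) * a21) - a01 * (a10 * (-g2) - (-g1) * a20)
              + (-g0) * (a10 * a21 - a11 * a20);
    double dz0 = d0 / det, dz1 = d1 / det, dz2 = d2 / det;
    double lam = 1.0;
    for (int k = 0; k < 40; ++k) {
      double t0 = z[0] + lam * dz0, t1 = z[1] + lam * dz1, t2 = z[2] + lam * dz2;
      if (t0 >= 0.0 && t1 >= 0.0 && t2 >= 0.0) { z[0] = t0; z[1] = t1; z[2] = t2; break; }
      lam *= 0.5;
      if (k == 39) { z[0] = std::max(t0, 0.0); z[1] = std::max(t1, 0.0); z[2] = std::max(t2, 0.0); }
    }
    if (!std::isfinite(z[0]) || !std::isfinite(z[1]) || !std::isfinite(z[2])) return false;
  }
  return false;                    // not converged
}

// Reaction step with dt-subdivision fallback.
static bool react_cell(double* z, const double* par, double dt, const Kin& kin,
                       double* c0, int depth) {
  double zs[3] = { z[0], z[1], z[2] };
  double cs = c0 ? *c0 : 0.0;
  if (newton_cell(z, par, dt, kin, c0)) return true;
  if (depth >= 8) return false;
  z[0] = zs[0]; z[1] = zs[1]; z[2] = zs[2];
  if (c0) *c0 = cs;
  return react_cell(z, par, 0.5 * dt, kin, c0, depth + 1)
      && react_cell(z, par, 0.5 * dt, kin, c0, depth + 1);
}

// ---------------------------------------------------------------------------
// tridiagonal (Thomas) solver; a = sub-, b = diag, c = super-diagonal

static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d, int n) {
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

static inline double harm(double a, double b) {
  return (a > 0.0 && b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
}

// axial velocity profile: strain gs below (h - w), gt in the tip window,
// rigid translation above the stalk top h
static inline double uvel(double y, double gs, double gt, double h, double w) {
  double a = std::max(h - w, 0.0);
  double u = gs * std::min(y, a);
  if (y > a) u += gt * (std::min(y, h) - a);
  return u;
}

// [[Rcpp::export]]
List rd_run(NumericVector xc, double hx, int Ny, double h0_stalk, List geom,
            NumericMatrix par_table, Nullable<NumericMatrix> mult_, List kin_,
            List bc_, List tim_, List growth_, NumericMatrix init) {
  const int Nx = xc.size();
  const int nc = Nx * Ny;
  const double hxi = 1.0 / Ny;
  Geom g = geom_from_list(geom);

  Kin kin;
  kin.n  = as<int>(kin_["n"]);
  kin.nS = as<int>(kin_["nS"]);
  kin.mP = as<int>(kin_["mP"]);
  kin.full = as<bool>(kin_["full"]);
  kin.kon  = kin.full ? as<double>(kin_["kon"]) : 0.0;
  kin.koff = kin.full ? as<double>(kin_["koff"]) : 0.0;

  const int bc_open = as<int>(bc_["open"]);       // 1: absorbing outer boundary
  NumericMatrix kx = bc_["kx"];                   // Ny x 3 impedance, left/right
  NumericMatrix ktop = bc_["ktop"];               // Nx x 3 impedance, top

  const double dt = as<double>(tim_["dt"]);
  const int nsteps = as<int>(tim_["nsteps"]);
  const int rec_every = as<int>(tim_["record_every"]);
  const double steady_tol = as<double>(tim_["steady_tol"]);
  const int check_every = as<int>(tim_["check_every"]);
  const bool stop_steady = as<bool>(tim_["stop_when_steady"]);
  const double steady_min_t = as<double>(tim_["steady_min_t"]);

  const bool grow = as<bool>(growth_["on"]);
  NumericVector Lv, gsv, gtv;
  double wtip = 0.0;
  if (grow) {
    Lv  = growth_["L"];                            // length nsteps+1
    gsv = growth_["gs"];                           // length nsteps
    gtv = growth_["gt"];
    wtip = as<double>(growth_["wtip"]);
  }
  const double L0 = as<double>(growth_["L0"]);     // total initial height

  // fields
  std::vector<double> F(nc), S(nc), P(nc), C(nc, 0.0);
  for (int i = 0; i < nc; ++i) { F[i] = init(i, 0); S[i] = init(i, 1); P[i] = init(i, 2); }
  if (kin.full && init.ncol() > 3) for (int i = 0; i < nc; ++i) C[i] = init(i, 3);

  // per-cell parameters
  std::vector<int> lab(nc);
  std::vector<double> par(nc * NPAR);
  NumericMatrix mult;
  bool has_mult = mult_.isNotNull();
  if (has_mult) mult = NumericMatrix(mult_);

  double L = grow ? Lv[0] : L0;
  double hst = h0_stalk;
  auto refresh_cells = [&](double hstalk, double Lcur) {
    for (int j = 0; j < Ny; ++j) {
      double y = (j + 0.5) * hxi * Lcur;
      for (int i = 0; i < Nx; ++i) {
        int id = i + j * Nx;
        int lb = point_label(xc[i], y, hstalk, g);
        lab[id] = lb;
        for (int k = 0; k < NPAR; ++k) {
          double v = par_table(lb - 1, k);
          if (has_mult) v *= mult(id, k);
          par[id * NPAR + k] = v;
        }
      }
    }
  };
  refresh_cells(hst, L);

  // recording
  std::vector<double> rec_t, rec_L, resid_t, resid_v;
  List frames;
  auto snapshot = [&](double t) {
    NumericMatrix fr(nc, kin.full ? 4 : 3);
    for (int i = 0; i < nc; ++i) { fr(i, 0) = F[i]; fr(i, 1) = S[i]; fr(i, 2) = P[i]; }
    if (kin.full) for (int i = 0; i < nc; ++i) fr(i, 3) = C[i];
    frames.push_back(fr);
    rec_t.push_back(t);
    rec_L.push_back(L);
  };
  snapshot(0.0);

  std::vector<double> Fp, Sp, Pp;                  // previous check state
  Fp = F; Sp = S; Pp = P;
  bool steady = false;
  bool failed = false;
  int steps_done = 0;

  std::vector<double> ta(std::max(Nx, Ny)), tb(std::max(Nx, Ny)),
                      tc(std::max(Nx, Ny)), td(std::max(Nx, Ny));
  std::vector<double> work(nc);

  for (int step = 0; step < nsteps && !steady && !failed; ++step) {
    double Lnew = grow ? Lv[step + 1] : L;
    double Ldot = grow ? (Lnew - L) / dt : 0.0;

    // (1) advection + dilution in xi
    if (grow && Ldot != 0.0) {
      double gs = gsv[step], gt = gtv[step];
      double* fld[3] = { F.data(), S.data(), P.data() };
      int nfld = 3;
      double* fld4[4] = { F.data(), S.data(), P.data(), C.data() };
      double** ff = fld;
      if (kin.full) { ff = fld4; nfld = 4; }
      for (int q = 0; q < nfld; ++q) {
        double* c = ff[q];
        for (int i = 0; i < Nx; ++i) {
          // fluxes on interior xi faces
          double prev_flux = 0.0;
          double carry = 0.0;                      // new value of cell j-1 pending
          for (int j = 0; j < Ny; ++j) {
            double flux = 0.0;
            if (j < Ny - 1) {
              double xif = (j + 1.0) * hxi;
              double w = uvel(xif * L, gs, gt, hst, wtip) - xif * Ldot;
              flux = (w > 0.0) ? w * c[i + j * Nx] : w * c[i + (j + 1) * Nx];
            }
            double cn = c[i + j * Nx]
              - dt / (L * hxi) * (flux - prev_flux)
              - dt * (Ldot / L) * c[i + j * Nx];
            if (j > 0) c[i + (j - 1) * Nx] = carry;
            carry = cn;
            prev_flux = flux;
          }
          c[i + (Ny - 1) * Nx] = carry;
        }
      }
      L = Lnew;
      hst = h0_stalk + (L - L0);
      refresh_cells(hst, L);
    }

    // (2) kinetics
    for (int id = 0; id < nc; ++id) {
      double z[3] = { F[id], S[id], P[id] };
      double c0 = C[id];
      if (!react_cell(z, &par[id * NPAR], dt, kin, kin.full ? &c0 : nullptr, 0)) {
        failed = true; break;
      }
      F[id] = z[0]; S[id] = z[1]; P[id] = z[2];
      if (kin.full) C[id] = c0;
    }
    if (failed) break;

    // (3) diffusion, species loop; parameter column 0,1,2 = Df, Ds, Dp
    for (int q = 0; q < 3; ++q) {
      double* c = (q == 0) ? F.data() : (q == 1) ? S.data() : P.data();
      int Dcol = q;
      // x sweep
      for (int j = 0; j < Ny; ++j) {
        for (int i = 0; i < Nx; ++i) {
          int id = i + j * Nx;
          double D = par[id * NPAR + Dcol];
          double aw = (i > 0) ? harm(par[(id - 1) * NPAR + Dcol], D) / (hx * hx) : 0.0;
          double ae = (i < Nx - 1) ? harm(par[(id + 1) * NPAR + Dcol], D) / (hx * hx) : 0.0;
          double rob = 0.0;
          if (bc_open == 1 && D > 0.0 && (i == 0 || i == Nx - 1))
            rob = kx(j, q) / hx;
          ta[i] = -dt * aw;
          tc[i] = -dt * ae;
          tb[i] = 1.0 + dt * (aw + ae + rob);
          td[i] = c[id];
        }
        thomas(ta, tb, tc, td, Nx);
        for (int i = 0; i < Nx; ++i) c[i + j * Nx] = td[i];
      }
      // xi sweep
      double h2 = hxi * hxi * L * L;
      for (int i = 0; i < Nx; ++i) {
        for (int j = 0; j < Ny; ++j) {
          int id = i + j * Nx;
          double D = par[id * NPAR + Dcol];
          double as = (j > 0) ? harm(par[(i + (j - 1) * Nx) * NPAR + Dcol], D) / h2 : 0.0;
          double an = (j < Ny - 1) ? harm(par[(i + (j + 1) * Nx) * NPAR + Dcol], D) / h2 : 0.0;
          double rob = 0.0;
          if (bc_open == 1 && D > 0.0 && j == Ny - 1) rob = ktop(i, q) / (hxi * L);
          ta[j] = -dt * as;
          tc[j] = -dt * an;
          tb[j] = 1.0 + dt * (as + an + rob);
          td[j] = c[id];
        }
        thomas(ta, tb, tc, td, Ny);
        for (int j = 0; j < Ny; ++j) c[i + j * Nx] = td[j];
      }
    }

    steps_done = step + 1;
    double t = steps_done * dt;

    if (check_every > 0 && steps_done % check_every == 0) {
      double r = 0.0;
      for (int i = 0; i < nc; ++i) {
        r = std::max(r, std::fabs(F[i] - Fp[i]));
        r = std::max(r, std::fabs(S[i] - Sp[i]));
        r = std::max(r, std::fabs(P[i] - Pp[i]));
      }
      r /= dt * check_every;
      resid_t.push_back(t);
      resid_v.push_back(r);
      Fp = F; Sp = S; Pp = P;
      if (!grow && stop_steady && r < steady_tol && t >= steady_min_t) steady = true;
      for (int i = 0; i < nc; ++i)
        if (!std::isfinite(F[i]) || !std::isfinite(S[i]) || !std::isfinite(P[i])) {
          failed = true; break;
        }
    }

    if (steps_done % rec_every == 0 || steady || steps_done == nsteps)
      snapshot(t);
  }

  IntegerMatrix labm(Nx, Ny);
  for (int j = 0; j < Ny; ++j)
    for (int i = 0; i < Nx; ++i) labm(i, j) = lab[i + j * Nx];

  return List::create(
    _["times"] = rec_t, _["L"] = rec_L, _["frames"] = frames,
    _["steady"] = steady, _["failed"] = failed,
    _["resid_times"] = resid_t, _["resid"] = resid_v,
    _["labels"] = labm, _["h_stalk"] = hst, _["steps"] = steps_done);
}
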