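// Compiled core: Bulirsch generalized complete elliptic integral, the
// surface-charge field of an axially magnetized cylinder, and the adaptive
// overdamped trajectory integrator behind the Monte-Carlo capture simulator.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bulirsch's cel(kc, p, c, s): generalized complete elliptic integral
//   cel = int_0^{pi/2} (c cos^2 + s sin^2) /
//         ((cos^2 + p sin^2) sqrt(cos^2 + kc^2 sin^2)) dphi
// Iterative arithmetic-geometric-mean style algorithm; kc must be nonzero.
static double cel(double kc, double p, double c, double s) {
  if (kc == 0.0) return NA_REAL;
  const double errtol = 1e-10;
  double k = std::fabs(kc), em = 1.0;
  double pp = p, cc = c, ss = s;
  if (p > 0.0) {
    pp = std::sqrt(p);
    ss = s / pp;
  } else {
    double f = kc * kc, q = 1.0 - f, g = 1.0 - pp;
    f -= pp;
    q *= (ss - c * pp);
    pp = std::sqrt(f / g);
    cc = (c - ss) / g;
    ss = -q / (g * g * pp) + cc * pp;
  }
  double f = cc;
  cc = cc + ss / pp;
  double g = k / pp;
  ss = 2.0 * (ss + f * g);
  pp = g + pp;
  g = em;
  em = k + em;
  double kk = k;
  while (std::fabs(g - k) > g * errtol) {
    k = 2.0 * std::sqrt(kk);
    kk = k * em;
    f = cc;
    cc = cc + ss / pp;
    g = kk / pp;
    ss = 2.0 * (ss + f * g);
    pp = g + pp;
    g = em;
    em = k + em;
  }
  return M_PI_2 * (ss + cc * em) / (em * (em + pp));
}

// Field of a uniformly magnetized cylinder, radius a, axial extent
// z in [-L, 0] (pole face at z = 0, magnetization +z, remanence Br).
// Coordinates: rho >= 0 radial, z axial distance from the pole-face plane.
// Returns (B_rho, B_z) in tesla. The ideal model is singular on the
// pole-face edge circle; points within `margin` of either edge are pushed
// radially to the margin distance and *flag is set.
static void cyl_field_rz(double rho, double z, double a, double L, double Br,
                         double margin, double *Brho, double *Bz, int *flag) {
  if (flag) *flag = 0;
  // distance to the near and far pole-face edge circles in the (rho,z) plane
  double dr = rho - a;
  double d_near = std::sqrt(dr * dr + z * z);
  double zf = z + L;
  double d_far = std::sqrt(dr * dr + zf * zf);
  if (d_near < margin || d_far < margin) {
    if (flag) *flag = 1;
    double zz = (d_near <= d_far) ? z : zf;
    double d = std::min(d_near, d_far);
    if (d < 1e-15) {
      rho = a + margin;  // exactly on the edge: push radially outward
    } else {
      double s = margin / d;
      rho = a + dr * s;
      double znew = zz * s;
      z = (d_near <= d_far) ? znew : (znew - L);
    }
  }
  // Derby & Olbert style evaluation; magnet centered at z = -L/2,
  // half-length b = L/2, so z' = z + L/2.
  double b = 0.5 * L;
  double zp = z + b;
  double zplus = zp + b;   // = z + L (far face)
  double zminus = zp - b;  // = z     (near face)
  double apr = a + rho, amr = a - rho;
  double den_p = std::sqrt(zplus * zplus + apr * apr);
  double den_m = std::sqrt(zminus * zminus + apr * apr);
  double alpha_p = a / den_p, alpha_m = a / den_m;
  double beta_p = zplus / den_p, beta_m = zminus / den_m;
  double gamma = amr / apr;
  double kp = std::sqrt((zplus * zplus + amr * amr) / (zplus * zplus + apr * apr));
  double km = std::sqrt((zminus * zminus + amr * amr) / (zminus * zminus + apr * apr));
  double B0 = Br / M_PI;
  double brho, bz;
  if (rho < 1e-12) {
    brho = 0.0;  // axisymmetry
    bz = 0.5 * Br * (zplus / std::sqrt(zplus * zplus + a * a) -
                     zminus / std::sqrt(zminus * zminus + a * a));
  } else {
    brho = B0 * (alpha_p * cel(kp, 1.0, 1.0, -1.0) -
                 alpha_m * cel(km, 1.0, 1.0, -1.0));
    bz = B0 * a / apr * (beta_p * cel(kp, gamma * gamma, 1.0, gamma) -
                         beta_m * cel(km, gamma * gamma, 1.0, gamma));
  }
  *Brho = brho;
  *Bz = bz;
}

// [[Rcpp::export(name = ".cel_cpp")]]
NumericVector cel_cpp(NumericVector kc, NumericVector p, NumericVector c,
                      NumericVector s) {
  R_xlen_t n = kc.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = cel(kc[i], p[i], c[i], s[i]);
  return out;
}

// Vectorized magnet-frame field; columns B_rho, B_z, clamped-flag.
// [[Rcpp::export(name = ".cyl_field_cpp")]]
NumericMatrix cyl_field_cpp(NumericVector rho, NumericVector z, double a,
                            double L, double Br, double margin) {
  R_xlen_t n = rho.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double brho, bz;
    int flag;
    cyl_field_rz(rho[i], z[i], a, L, Br, margin, &brho, &bz, &flag);
    out(i, 0) = brho;
    out(i, 1) = bz;
    out(i, 2) = flag;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trajectory integration
// ---------------------------------------------------------------------------

struct SimParams {
  // tube: axis along lab x from 0 to Lt, lumen radius Rt
  double Rt, Lt;
  // magnet pose: pole-face center o, unit axis u (pointing into the fluid)
  double o[3], u[3];
  double a, L, Br, margin;
  // flow
  double vbar;
  int profile;  // 0 poiseuille, 1 plug
  // field source: 0 cylinder magnet, 1 uniform |B|-gradient stub
  int field_type;
  double gvec[3];  // uniform grad|B| (T/m), field_type 1
  double B0;       // |B| used for the moment under the uniform stub
  // capture geometry
  double footprint_radius;  // lateral distance from magnet axis
  double capture_dir[3];    // unit vector, tube axis -> magnet side
  // numerics
  double rtol, atol, h_disp_max;
  int max_steps;
  double grad_h;
};

static double bmag_at(const SimParams &P, const double p[3]) {
  double q0 = p[0] - P.o[0], q1 = p[1] - P.o[1], q2 = p[2] - P.o[2];
  double zm = q0 * P.u[0] + q1 * P.u[1] + q2 * P.u[2];
  double r0 = q0 - zm * P.u[0], r1 = q1 - zm * P.u[1], r2 = q2 - zm * P.u[2];
  double rm = std::sqrt(r0 * r0 + r1 * r1 + r2 * r2);
  double brho, bz;
  cyl_field_rz(rm, zm, P.a, P.L, P.Br, P.margin, &brho, &bz, nullptr);
  return std::sqrt(brho * brho + bz * bz);
}

// grad|B| by central differences (step grad_h); returns |B| at p.
static double grad_bmag(const SimParams &P, const double p[3], double g[3]) {
  if (P.field_type == 1) {
    g[0] = P.gvec[0]; g[1] = P.gvec[1]; g[2] = P.gvec[2];
    return P.B0;
  }
  double q[3];
  for (int i = 0; i < 3; ++i) {
    q[0] = p[0]; q[1] = p[1]; q[2] = p[2];
    q[i] = p[i] + P.grad_h;
    double bp = bmag_at(P, q);
    q[i] = p[i] - P.grad_h;
    double bm = bmag_at(P, q);
    g[i] = (bp - bm) / (2.0 * P.grad_h);
  }
  return bmag_at(P, p);
}

struct CellParams {
  double diam, msat, mobility;  // mobility = 1/(3 pi eta d)
  int model;                    // 0 saturated, 1 langevin
  double xi_per_T;              // particle moment / (kB T)
};

static double moment_of(const CellParams &C, double Bmag) {
  if (C.model == 0) return C.msat;
  double xi = C.xi_per_T * Bmag;
  if (xi < 1e-6) return C.msat * xi / 3.0;
  return C.msat * (1.0 / std::tanh(xi) - 1.0 / xi);
}

static void rhs(const SimParams &P, const CellParams &C, const double p[3],
                double v[3]) {
  double rho2 = p[1] * p[1] + p[2] * p[2];
  double vx;
  if (P.profile == 1) {
    vx = P.vbar;
  } else {
    double f = 1.0 - rho2 / (P.Rt * P.Rt);
    vx = 2.0 * P.vbar * (f > 0.0 ? f : 0.0);
  }
  double g[3];
  double Bmag = grad_bmag(P, p, g);
  double m = moment_of(C, Bmag);
  double k = m * C.mobility;
  v[0] = vx + k * g[0];
  v[1] = k * g[1];
  v[2] = k * g[2];
}

// Cash-Karp RK45 embedded pair
static const double CK_A[6] = {0.0, 0.2, 0.3, 0.6, 1.0, 0.875};
static const double CK_B[6][5] = {
    {0, 0, 0, 0, 0},
    {0.2, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0},
    {0.3, -0.9, 1.2, 0, 0},
    {-11.0 / 54, 2.5, -70.0 / 27, 35.0 / 27, 0},
    {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
     253.0 / 4096}};
static const double CK_C5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                                512.0 / 1771};
static const double CK_C4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 0.25};

// One adaptive step from y (modified in place); returns accepted h and sets
// *hnext. err based on mixed abs/rel tolerance on position.
static double ck_step(const SimParams &P, const CellParams &C, double y[3],
                      double h, double *hnext) {
  double k[6][3], ytmp[3], y5[3], y4[3];
  for (;;) {
    rhs(P, C, y, k[0]);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < 3; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += CK_B[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      rhs(P, C, ytmp, k[s]);
    }
    double err = 0.0;
    for (int i = 0; i < 3; ++i) {
      double s5 = 0.0, s4 = 0.0;
      for (int j = 0; j < 6; ++j) {
        s5 += CK_C5[j] * k[j][i];
        s4 += CK_C4[j] * k[j][i];
      }
      y5[i] = y[i] + h * s5;
      y4[i] = y[i] + h * s4;
      double sc = P.atol + P.rtol * std::fabs(y5[i]);
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > err) err = e;
    }
    if (err <= 1.0 || h <= 1e-12) {
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      *hnext = h * fac;
      y[0] = y5[0]; y[1] = y5[1]; y[2] = y5[2];
      return h;
    }
    double fac = 0.9 * std::pow(err, -0.25);
    if (fac < 0.1) fac = 0.1;
    h *= fac;
  }
}

// lateral distance of point p from the magnet axis line (through o along u)
static double lateral_dist(const SimParams &P, const double p[3]) {
  double q0 = p[0] - P.o[0], q1 = p[1] - P.o[1], q2 = p[2] - P.o[2];
  double zm = q0 * P.u[0] + q1 * P.u[1] + q2 * P.u[2];
  double r0 = q0 - zm * P.u[0], r1 = q1 - zm * P.u[1], r2 = q2 - zm * P.u[2];
  return std::sqrt(r0 * r0 + r1 * r1 + r2 * r2);
}

static bool is_captured_contact(const SimParams &P, const double p[3]) {
  if (lateral_dist(P, p) > P.footprint_radius) return false;
  // contact must be on the wall half facing the magnet
  double side = p[1] * P.capture_dir[1] + p[2] * P.capture_dir[2];
  return side > 0.0;
}

// Integrate one cell. fate: 0 exited, 1 captured, 2 flagged (step budget).
// out: fate, t, x, y, z. If rec != nullptr, accepted states are appended.
static void run_cell(const SimParams &P, const CellParams &C,
                     const double inlet[3], double out[5],
                     std::vector<double> *rec) {
  double y[3] = {inlet[0], inlet[1], inlet[2]};
  double rho_max = P.Rt - 0.5 * C.diam;
  double t = 0.0;
  // initial step from local speed
  double v0[3];
  rhs(P, C, y, v0);
  double sp = std::sqrt(v0[0] * v0[0] + v0[1] * v0[1] + v0[2] * v0[2]);
  double h = (sp > 0.0) ? 0.05 * P.h_disp_max / sp : 1e-3;
  int fate = 2;
  bool sliding = false;
  if (rec) {
    rec->push_back(t); rec->push_back(y[0]);
    rec->push_back(y[1]); rec->push_back(y[2]);
  }
  // cell seeded already on/through the wall
  if (std::sqrt(y[1] * y[1] + y[2] * y[2]) >= rho_max) {
    if (is_captured_contact(P, y)) {
      out[0] = 1; out[1] = 0; out[2] = y[0]; out[3] = y[1]; out[4] = y[2];
      return;
    }
    double r = std::sqrt(y[1] * y[1] + y[2] * y[2]);
    double s = (rho_max * (1.0 - 1e-9)) / r;
    y[1] *= s; y[2] *= s;
    sliding = true;
  }
  for (int step = 0; step < P.max_steps; ++step) {
    if (sliding) {
      // Wall-contact mode: the drift presses the cell against the lumen
      // wall outside the capture footprint; advance with the velocity
      // projected onto the wall (midpoint rule, re-clamped for curvature)
      // until the cell is released, enters the footprint, or exits.
      double v[3];
      rhs(P, C, y, v);
      double rho = std::sqrt(y[1] * y[1] + y[2] * y[2]);
      double nhat1 = y[1] / rho, nhat2 = y[2] / rho;
      double vn = v[1] * nhat1 + v[2] * nhat2;
      if (vn <= 0.0) { sliding = false; continue; }  // released from the wall
      double vt[3] = {v[0], v[1] - vn * nhat1, v[2] - vn * nhat2};
      double spd = std::sqrt(vt[0] * vt[0] + vt[1] * vt[1] + vt[2] * vt[2]);
      if (spd < 1e-15) break;  // pinned: no tangential transport (flagged)
      double hs = P.h_disp_max / spd;
      // midpoint evaluation, projected again
      double ym[3] = {y[0] + 0.5 * hs * vt[0], y[1] + 0.5 * hs * vt[1],
                      y[2] + 0.5 * hs * vt[2]};
      double rm = std::sqrt(ym[1] * ym[1] + ym[2] * ym[2]);
      if (rm > 0) {
        double s = (rho_max * (1.0 - 1e-9)) / rm;
        ym[1] *= s; ym[2] *= s;
      }
      double vmid[3];
      rhs(P, C, ym, vmid);
      double rhom = std::sqrt(ym[1] * ym[1] + ym[2] * ym[2]);
      double n1 = ym[1] / rhom, n2 = ym[2] / rhom;
      double vnm = vmid[1] * n1 + vmid[2] * n2;
      if (vnm > 0.0) { vmid[1] -= vnm * n1; vmid[2] -= vnm * n2; }
      y[0] += hs * vmid[0]; y[1] += hs * vmid[1]; y[2] += hs * vmid[2];
      double rnew = std::sqrt(y[1] * y[1] + y[2] * y[2]);
      if (rnew > 0) {
        double s = (rho_max * (1.0 - 1e-9)) / rnew;
        y[1] *= s; y[2] *= s;
      }
      t += hs;
      if (rec) {
        rec->push_back(t); rec->push_back(y[0]);
        rec->push_back(y[1]); rec->push_back(y[2]);
      }
      if (is_captured_contact(P, y)) { fate = 1; break; }
      if (y[0] >= P.Lt) { fate = 0; break; }
      continue;
    }
    double yprev[3] = {y[0], y[1], y[2]};
    double tprev = t;
    // cap step so displacement stays resolvable against the geometry
    double vloc[3];
    rhs(P, C, y, vloc);
    double spd = std::sqrt(vloc[0] * vloc[0] + vloc[1] * vloc[1] +
                           vloc[2] * vloc[2]);
    if (spd > 0.0 && h * spd > P.h_disp_max) h = P.h_disp_max / spd;
    double hnext;
    double hdid = ck_step(P, C, y, h, &hnext);
    t += hdid;
    h = hnext;
    double rho = std::sqrt(y[1] * y[1] + y[2] * y[2]);
    if (rho >= rho_max) {
      // locate the crossing on the step chord (bisection on the segment)
      double lo = 0.0, hi = 1.0, c[3];
      for (int it = 0; it < 40; ++it) {
        double mid = 0.5 * (lo + hi);
        for (int i = 0; i < 3; ++i) c[i] = yprev[i] + mid * (y[i] - yprev[i]);
        double r = std::sqrt(c[1] * c[1] + c[2] * c[2]);
        if (r >= rho_max) hi = mid; else lo = mid;
      }
      for (int i = 0; i < 3; ++i) c[i] = yprev[i] + hi * (y[i] - yprev[i]);
      // if the outlet was reached earlier on this chord, the cell exited
      if (y[0] >= P.Lt) {
        double s_exit = (P.Lt - yprev[0]) / (y[0] - yprev[0]);
        if (s_exit < hi) {
          t = tprev + s_exit * hdid;
          y[0] = P.Lt; y[1] = yprev[1] + s_exit * (y[1] - yprev[1]);
          y[2] = yprev[2] + s_exit * (y[2] - yprev[2]);
          fate = 0;
          break;
        }
      }
      t = tprev + hi * hdid;
      if (is_captured_contact(P, c)) {
        fate = 1;
        y[0] = c[0]; y[1] = c[1]; y[2] = c[2];
        break;
      }
      // non-capturing contact: clamp just inside the wall and slide
      double r = std::sqrt(c[1] * c[1] + c[2] * c[2]);
      double s = (rho_max * (1.0 - 1e-9)) / r;
      y[0] = c[0]; y[1] = c[1] * s; y[2] = c[2] * s;
      sliding = true;
    }
    if (rec) {
      rec->push_back(t); rec->push_back(y[0]);
      rec->push_back(y[1]); rec->push_back(y[2]);
    }
    if (y[0] >= P.Lt) { fate = 0; break; }
  }
  out[0] = fate; out[1] = t; out[2] = y[0]; out[3] = y[1]; out[4] = y[2];
}

static SimParams build_params(List cfg) {
  SimParams P;
  P.Rt = cfg["tube_radius"];
  P.Lt = cfg["tube_length"];
  NumericVector o = cfg["magnet_origin"], u = cfg["magnet_axis"],
                cd = cfg["capture_dir"], gv = cfg["grad_stub"];
  for (int i = 0; i < 3; ++i) {
    P.o[i] = o[i]; P.u[i] = u[i]; P.capture_dir[i] = cd[i]; P.gvec[i] = gv[i];
  }
  P.a = cfg["magnet_radius"];
  P.L = cfg["magnet_length"];
  P.Br = cfg["remanence"];
  P.margin = cfg["edge_margin"];
  P.vbar = cfg["mean_velocity"];
  P.profile = cfg["profile"];
  P.field_type = cfg["field_type"];
  P.B0 = cfg["stub_bmag"];
  P.footprint_radius = cfg["footprint_radius"];
  P.rtol = cfg["rtol"];
  P.atol = cfg["atol"];
  P.h_disp_max = cfg["max_step_disp"];
  P.max_steps = cfg["max_steps"];
  P.grad_h = cfg["grad_h"];
  return P;
}

// inlet: n x 3 lab positions; diam/msat: per-cell; eta: viscosity.
// Returns n x 5 matrix (fate, t, x, y, z).
// [[Rcpp::export(name = ".simulate_capture_cpp")]]
NumericMatrix simulate_capture_cpp(NumericMatrix inlet, NumericVector diam,
                                   NumericVector msat, double eta,
                                   int moment_model, double xi_per_T,
                                   List cfg) {
  SimParams P = build_params(cfg);
  R_xlen_t n = inlet.nrow();
  NumericMatrix out(n, 5);
  for (R_xlen_t i = 0; i < n; ++i) {
    CellParams C;
    C.diam = diam[i];
    C.msat = msat[i];
    C.mobility = 1.0 / (3.0 * M_PI * eta * diam[i]);
    C.model = moment_model;
    C.xi_per_T = xi_per_T;
    double in[3] = {inlet(i, 0), inlet(i, 1), inlet(i, 2)};
    double res[5];
    run_cell(P, C, in, res, nullptr);
    for (int j = 0; j < 5; ++j) out(i, j) = res[j];
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Single-cell version recording the accepted states.
// Returns list(fate, t_end, path = k x 4 matrix (t, x, y, z)).
// [[Rcpp::export(name = ".trajectory_cpp")]]
List trajectory_cpp(NumericVector inlet, double diam, double msat, double eta,
                    int moment_model, double xi_per_T, List cfg) {
  SimParams P = build_params(cfg);
  CellParams C;
  C.diam = diam;
  C.msat = msat;
  C.mobility = 1.0 / (3.0 * M_PI * eta * diam);
  C.model = moment_model;
  C.xi_per_T = xi_per_T;
  double in[3] = {inlet[0], inlet[1], inlet[2]};
  double res[5];
  std::vector<double> rec;
  run_cell(P, C, in, res, &rec);
  R_xlen_t k = rec.size() / 4;
  NumericMatrix path(k, 4);
  for (R_xlen_t i = 0; i < k; ++i)
    for (int j = 0; j < 4; ++j) path(i, j) = rec[4 * i + j];
  colnames(path) = CharacterVector::create("t", "x", "y", "z");
  return List::create(_["fate"] = res[0], _["t_end"] = res[1],
                      _["end"] = NumericVector::create(res[2], res[3], res[4]),
                      _["path"] = path);
}
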