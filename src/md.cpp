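// Reduced MD engine for the selectivity-filter model.
//
// Internal unit system: length pm, time fs, mass u (Da), charge e.
// Energy unit is then u pm^2 fs^-2 (1 eV = 96.4853322 of these); all
// conversions happen on the R side, this file only sees internal units.
//
// Degrees of freedom:
//   * 24 carbonyl rotors: unit C->O orientation u with angular velocity w
//     perpendicular to u (2 DOF each); carbon positions are fixed.
//   * mobile particles on the pore axis: K+ (z, vz) and rigid waters
//     (z, vz plus a rigid-rotor orientation frame {e1, e2, d} with angular
//     velocity vector om and isotropic moment of inertia).
//
// Integration is velocity Verlet; orientations advance by exact Rodrigues
// rotation about the angular-velocity axis and are renormalized.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const int KIND_C = 0, KIND_OC = 1, KIND_LP = 2,
                 KIND_K = 3, KIND_OW = 4, KIND_HW = 5;
static const int N_KIND = 6;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64: a single counter-style generator
// so that identical seeds give bit-identical trajectories.
struct RNG {
  uint64_t s[4];
  bool have_gauss;
  double gauss_cache;
  explicit RNG(uint64_t seed) : have_gauss(false), gauss_cache(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  double gauss() {
    if (have_gauss) { have_gauss = false; return gauss_cache; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925287 * u2;
    gauss_cache = r * std::sin(a);
    have_gauss = true;
    return r * std::cos(a);
  }
};

// ------------------------------------------------------------- helpers ----
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Rodrigues rotation of v about unit axis k by angle a (in place).
static inline void rotate3(double* v, const double* k, double a) {
  double c = std::cos(a), s = std::sin(a);
  double kv[3];
  cross3(k, v, kv);
  double kd = k[0] * v[0] + k[1] * v[1] + k[2] * v[2];
  double om = 1.0 - c;
  v[0] = v[0] * c + kv[0] * s + k[0] * kd * om;
  v[1] = v[1] * c + kv[1] * s + k[1] * kd * om;
  v[2] = v[2] * c + kv[2] * s + k[2] * kd * om;
}

static inline void normalize3(double* v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (n > 0) { v[0] /= n; v[1] /= n; v[2] /= n; }
}

// ---------------------------------------------------------------- data ----
struct Mobile {
  int species;                 // 0 = K+, 1 = water
  double z, vz;
  double d[3], e1[3], om[3];   // water orientation frame + angular velocity
  int id;
};

struct Params {
  int ncarb;
  std::vector<double> cx, cy, cz;       // fixed carbon positions
  std::vector<double> u0x, u0y, u0z;    // rest orientations
  double r_co, lp_off;
  double q_c, q_o, q_lp;
  double kappa, i_c;
  double q_k, m_k;
  double q_wo, q_wh, m_w, i_w;
  double w_ooff, w_hpar, w_hperp;       // rigid water site offsets from COM
  double ke2;                           // Coulomb constant * e^2, internal
  double rep_b, rep_rho, rep_cut;       // Born-Mayer repulsion, shifted-force
  double contact[N_KIND][N_KIND];       // contact distances; 0 = no repulsion
  double e_field;                       // axial force per unit charge e
  double dt, kt;
  double thermo_prob;                   // per carbonyl per step
  double inj_rate;                      // attempts per fs
  double clearance, z_cav, z_exit, z_floor;
  bool coupling, injection_on, boundaries_on;
  long long n_therm, n_prod;
  uint64_t seed;
  std::vector<int> rec_idx;             // carbonyls whose O positions to log
  long long rec_stride, snap_stride, energy_stride;
};

struct Forces {
  std::vector<double> tcx, tcy, tcz;    // carbonyl torques
  std::vector<double> fmz;              // axial force on mobiles
  std::vector<double> twx, twy, twz;    // water torques
  // full 3D force on each mobile before axial projection (diagnostics)
  std::vector<double> fm3x, fm3y, fm3z;
  double pe, pe_coul, pe_rep, pe_bend, pe_field;
};

struct Sys {
  Params P;
  std::vector<double> ux, uy, uz, wx, wy, wz;
  std::vector<Mobile> mob;
  double t;
  RNG rng;
  double e_cc;                          // constant C-C Coulomb energy
  int next_id;
  long long order_violations;
  // scratch point buffers
  std::vector<double> px, py, pz, pq, fx, fy, fz;
  std::vector<int> pkind, powner;
  Sys(uint64_t seed) : t(0.0), rng(seed), e_cc(0.0), next_id(0),
                       order_violations(0) {}
};

// -------------------------------------------------------- param parsing ---
static Params parse_params(List P_) {
  Params P;
  NumericMatrix cc = P_["carbons"], u0 = P_["rest_orientations"];
  P.ncarb = cc.nrow();
  P.cx.resize(P.ncarb); P.cy.resize(P.ncarb); P.cz.resize(P.ncarb);
  P.u0x.resize(P.ncarb); P.u0y.resize(P.ncarb); P.u0z.resize(P.ncarb);
  for (int i = 0; i < P.ncarb; ++i) {
    P.cx[i] = cc(i, 0); P.cy[i] = cc(i, 1); P.cz[i] = cc(i, 2);
    P.u0x[i] = u0(i, 0); P.u0y[i] = u0(i, 1); P.u0z[i] = u0(i, 2);
  }
  P.r_co = P_["r_co"]; P.lp_off = P_["lp_off"];
  P.q_c = P_["q_c"]; P.q_o = P_["q_o"]; P.q_lp = P_["q_lp"];
  P.kappa = P_["kappa"]; P.i_c = P_["i_c"];
  P.q_k = P_["q_k"]; P.m_k = P_["m_k"];
  P.q_wo = P_["q_wo"]; P.q_wh = P_["q_wh"];
  P.m_w = P_["m_w"]; P.i_w = P_["i_w"];
  P.w_ooff = P_["w_ooff"]; P.w_hpar = P_["w_hpar"]; P.w_hperp = P_["w_hperp"];
  P.ke2 = P_["ke2"];
  P.rep_b = P_["rep_b"]; P.rep_rho = P_["rep_rho"]; P.rep_cut = P_["rep_cut"];
  NumericMatrix cm = P_["contact"];
  for (int i = 0; i < N_KIND; ++i)
    for (int j = 0; j < N_KIND; ++j) P.contact[i][j] = cm(i, j);
  P.e_field = P_["e_field"];
  P.dt = P_["dt"]; P.kt = P_["kt"];
  P.thermo_prob = P_["thermo_prob"];
  P.inj_rate = P_["inj_rate"];
  P.clearance = P_["clearance"];
  P.z_cav = P_["z_cav"]; P.z_exit = P_["z_exit"]; P.z_floor = P_["z_floor"];
  P.coupling = P_["coupling"];
  P.injection_on = P_["injection_on"];
  P.boundaries_on = P_["boundaries_on"];
  P.n_therm = (long long)Rf_asReal(P_["n_therm"]);
  P.n_prod = (long long)Rf_asReal(P_["n_prod"]);
  P.seed = (uint64_t)Rf_asReal(P_["seed"]);
  IntegerVector ri = P_["rec_idx"];
  P.rec_idx.assign(ri.begin(), ri.end());
  P.rec_stride = (long long)Rf_asReal(P_["rec_stride"]);
  P.snap_stride = (long long)Rf_asReal(P_["snap_stride"]);
  P.energy_stride = (long long)Rf_asReal(P_["energy_stride"]);
  return P;
}

static void load_state(Sys& S, List S_) {
  const Params& P = S.P;
  NumericMatrix u = S_["u"], w = S_["w"];
  S.ux.resize(P.ncarb); S.uy.resize(P.ncarb); S.uz.resize(P.ncarb);
  S.wx.resize(P.ncarb); S.wy.resize(P.ncarb); S.wz.resize(P.ncarb);
  for (int i = 0; i < P.ncarb; ++i) {
    S.ux[i] = u(i, 0); S.uy[i] = u(i, 1); S.uz[i] = u(i, 2);
    S.wx[i] = w(i, 0); S.wy[i] = w(i, 1); S.wz[i] = w(i, 2);
  }
  IntegerVector sp = S_["mob_species"], id = S_["mob_id"];
  NumericVector z = S_["mob_z"], vz = S_["mob_vz"];
  NumericMatrix d = S_["mob_d"], e1 = S_["mob_e1"], om = S_["mob_om"];
  int n = sp.size();
  S.mob.clear();
  for (int i = 0; i < n; ++i) {
    Mobile m;
    m.species = sp[i]; m.z = z[i]; m.vz = vz[i]; m.id = id[i];
    for (int k = 0; k < 3; ++k) {
      m.d[k] = d(i, k); m.e1[k] = e1(i, k); m.om[k] = om(i, k);
    }
    S.mob.push_back(m);
  }
  std::sort(S.mob.begin(), S.mob.end(),
            [](const Mobile& a, const Mobile& b) { return a.z < b.z; });
  S.t = Rf_asReal(S_["t"]);
  S.next_id = 0;
  for (int i = 0; i < n; ++i) S.next_id = std::max(S.next_id, (int)id[i] + 1);
}

// Constant Coulomb energy among the fixed carbons (no force consequence).
static double carbon_carbon_energy(const Params& P) {
  double e = 0.0;
  if (!P.coupling) return 0.0;
  for (int i = 0; i < P.ncarb; ++i)
    for (int j = i + 1; j < P.ncarb; ++j) {
      double dx = P.cx[i] - P.cx[j], dy = P.cy[i] - P.cy[j],
             dz = P.cz[i] - P.cz[j];
      e += P.ke2 * P.q_c * P.q_c / std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  return e;
}

// ------------------------------------------------------- force assembly ---
static void build_points(Sys& S) {
  const Params& P = S.P;
  int npt = 3 * P.ncarb;
  for (size_t m = 0; m < S.mob.size(); ++m)
    npt += (S.mob[m].species == 0) ? 1 : 3;
  S.px.resize(npt); S.py.resize(npt); S.pz.resize(npt);
  S.pq.resize(npt); S.pkind.resize(npt); S.powner.resize(npt);
  int n = P.ncarb;
  for (int c = 0; c < n; ++c) {
    S.px[c] = P.cx[c]; S.py[c] = P.cy[c]; S.pz[c] = P.cz[c];
    S.pq[c] = P.q_c; S.pkind[c] = KIND_C; S.powner[c] = c;
    double ox = P.cx[c] + P.r_co * S.ux[c];
    double oy = P.cy[c] + P.r_co * S.uy[c];
    double oz = P.cz[c] + P.r_co * S.uz[c];
    S.px[n + c] = ox; S.py[n + c] = oy; S.pz[n + c] = oz;
    S.pq[n + c] = P.q_o; S.pkind[n + c] = KIND_OC; S.powner[n + c] = c;
    double lr = P.r_co + P.lp_off;
    S.px[2 * n + c] = P.cx[c] + lr * S.ux[c];
    S.py[2 * n + c] = P.cy[c] + lr * S.uy[c];
    S.pz[2 * n + c] = P.cz[c] + lr * S.uz[c];
    S.pq[2 * n + c] = P.q_lp; S.pkind[2 * n + c] = KIND_LP;
    S.powner[2 * n + c] = c;
  }
  int at = 3 * n;
  for (size_t m = 0; m < S.mob.size(); ++m) {
    const Mobile& M = S.mob[m];
    int owner = 1000 + (int)m;
    if (M.species == 0) {
      S.px[at] = 0; S.py[at] = 0; S.pz[at] = M.z;
      S.pq[at] = P.q_k; S.pkind[at] = KIND_K; S.powner[at] = owner;
      ++at;
    } else {
      // O site: COM - w_ooff * d
      S.px[at] = -P.w_ooff * M.d[0];
      S.py[at] = -P.w_ooff * M.d[1];
      S.pz[at] = M.z - P.w_ooff * M.d[2];
      S.pq[at] = P.q_wo; S.pkind[at] = KIND_OW; S.powner[at] = owner;
      ++at;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        S.px[at] = P.w_hpar * M.d[0] + sgn * P.w_hperp * M.e1[0];
        S.py[at] = P.w_hpar * M.d[1] + sgn * P.w_hperp * M.e1[1];
        S.pz[at] = M.z + P.w_hpar * M.d[2] + sgn * P.w_hperp * M.e1[2];
        S.pq[at] = P.q_wh; S.pkind[at] = KIND_HW; S.powner[at] = owner;
        ++at;
      }
    }
  }
}

static void compute_forces(Sys& S, Forces& F) {
  const Params& P = S.P;
  build_points(S);
  int npt = (int)S.px.size();
  S.fx.assign(npt, 0.0); S.fy.assign(npt, 0.0); S.fz.assign(npt, 0.0);
  double pe_coul = 0.0, pe_rep = 0.0;
  const double rc = P.rep_cut, rho = P.rep_rho, B = P.rep_b;
  const double ecut = std::exp(-rc / rho);
  for (int i = 0; i < npt; ++i) {
    const double xi = S.px[i], yi = S.py[i], zi = S.pz[i], qi = S.pq[i];
    const int ki = S.pkind[i], oi = S.powner[i];
    double fxi = 0, fyi = 0, fzi = 0;
    for (int j = i + 1; j < npt; ++j) {
      if (S.powner[j] == oi) continue;
      const int kj = S.pkind[j];
      if (ki == KIND_C && kj == KIND_C) continue;   // constant, precomputed
      if (!P.coupling && oi < 1000 && S.powner[j] < 1000) continue;
      double dx = xi - S.px[j], dy = yi - S.py[j], dz = zi - S.pz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r <= 1e-6)
        stop("singular configuration: coincident charges at t = %f fs", S.t);
      double e = P.ke2 * qi * S.pq[j] / r;
      pe_coul += e;
      double fr = e / r2;                            // |F|/r
      double c0 = P.contact[ki][kj];
      if (c0 > 0.0 && r < rc) {
        // shifted-force Born-Mayer: zero value and slope at the cutoff
        double a = B * std::exp(c0 / rho);
        double er = std::exp(-r / rho);
        pe_rep += a * (er - ecut) + (r - rc) * (a / rho) * ecut;
        fr += (a / rho) * (er - ecut) / r;
      }
      double gx = fr * dx, gy = fr * dy, gz = fr * dz;
      fxi += gx; fyi += gy; fzi += gz;
      S.fx[j] -= gx; S.fy[j] -= gy; S.fz[j] -= gz;
    }
    S.fx[i] += fxi; S.fy[i] += fyi; S.fz[i] += fzi;
  }
  // uniform axial driving field (acts on every charged point)
  double pe_field = 0.0;
  if (P.e_field != 0.0) {
    for (int i = 0; i < npt; ++i) {
      S.fz[i] += S.pq[i] * P.e_field;
      pe_field -= S.pq[i] * P.e_field * S.pz[i];
    }
  }
  // carbonyl torques: from O and lone-pair site forces plus harmonic bending
  int n = P.ncarb;
  F.tcx.assign(n, 0.0); F.tcy.assign(n, 0.0); F.tcz.assign(n, 0.0);
  double pe_bend = 0.0;
  for (int c = 0; c < n; ++c) {
    double u[3] = { S.ux[c], S.uy[c], S.uz[c] };
    double rO[3] = { P.r_co * u[0], P.r_co * u[1], P.r_co * u[2] };
    double rL = P.r_co + P.lp_off;
    double rLp[3] = { rL * u[0], rL * u[1], rL * u[2] };
    double fO[3] = { S.fx[n + c], S.fy[n + c], S.fz[n + c] };
    double fL[3] = { S.fx[2 * n + c], S.fy[2 * n + c], S.fz[2 * n + c] };
    double t1[3], t2[3];
    cross3(rO, fO, t1);
    cross3(rLp, fL, t2);
    double u0[3] = { P.u0x[c], P.u0y[c], P.u0z[c] };
    double cr[3];
    cross3(u0, u, cr);
    double s = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
    double dthx = 0, dthy = 0, dthz = 0, th = 0;
    if (s > 1e-14) {
      double dotv = u0[0] * u[0] + u0[1] * u[1] + u0[2] * u[2];
      th = std::atan2(s, dotv);
      double fac = -P.kappa * th / s;
      dthx = fac * cr[0]; dthy = fac * cr[1]; dthz = fac * cr[2];
    }
    pe_bend += 0.5 * P.kappa * th * th;
    F.tcx[c] = t1[0] + t2[0] + dthx;
    F.tcy[c] = t1[1] + t2[1] + dthy;
    F.tcz[c] = t1[2] + t2[2] + dthz;
  }
  // mobile forces and water torques
  int nm = (int)S.mob.size();
  F.fmz.assign(nm, 0.0);
  F.twx.assign(nm, 0.0); F.twy.assign(nm, 0.0); F.twz.assign(nm, 0.0);
  F.fm3x.assign(nm, 0.0); F.fm3y.assign(nm, 0.0); F.fm3z.assign(nm, 0.0);
  int at = 3 * n;
  for (int m = 0; m < nm; ++m) {
    const Mobile& M = S.mob[m];
    if (M.species == 0) {
      F.fmz[m] = S.fz[at];
      F.fm3x[m] = S.fx[at]; F.fm3y[m] = S.fy[at]; F.fm3z[m] = S.fz[at];
      ++at;
    } else {
      double fzsum = 0, tx = 0, ty = 0, tz = 0;
      for (int ssite = 0; ssite < 3; ++ssite) {
        double rr[3] = { S.px[at], S.py[at], S.pz[at] - M.z };
        double ff[3] = { S.fx[at], S.fy[at], S.fz[at] };
        double tq[3];
        cross3(rr, ff, tq);
        tx += tq[0]; ty += tq[1]; tz += tq[2];
        fzsum += ff[2];
        F.fm3x[m] += ff[0]; F.fm3y[m] += ff[1]; F.fm3z[m] += ff[2];
        ++at;
      }
      F.fmz[m] = fzsum;
      F.twx[m] = tx; F.twy[m] = ty; F.twz[m] = tz;
    }
  }
  F.pe_coul = pe_coul + S.e_cc;
  F.pe_rep = pe_rep;
  F.pe_bend = pe_bend;
  F.pe_field = pe_field;
  F.pe = F.pe_coul + pe_rep + pe_bend + pe_field;
  if (!std::isfinite(F.pe))
    stop("numeric blow-up: non-finite potential energy at t = %f fs", S.t);
}

static double kinetic_carb(const Sys& S) {
  double ke = 0.0;
  for (int c = 0; c < S.P.ncarb; ++c)
    ke += 0.5 * S.P.i_c * (S.wx[c] * S.wx[c] + S.wy[c] * S.wy[c] +
                           S.wz[c] * S.wz[c]);
  return ke;
}

static void kinetic_mob(const Sys& S, double* trans, double* rot) {
  double kt = 0.0, kr = 0.0;
  for (const Mobile& M : S.mob) {
    double m = (M.species == 0) ? S.P.m_k : S.P.m_w;
    kt += 0.5 * m * M.vz * M.vz;
    if (M.species == 1)
      kr += 0.5 * S.P.i_w * (M.om[0] * M.om[0] + M.om[1] * M.om[1] +
                             M.om[2] * M.om[2]);
  }
  *trans = kt; *rot = kr;
}

// ------------------------------------------------------------ stepping ----
static inline void project_w(Sys& S, int c) {
  double d = S.wx[c] * S.ux[c] + S.wy[c] * S.uy[c] + S.wz[c] * S.uz[c];
  S.wx[c] -= d * S.ux[c]; S.wy[c] -= d * S.uy[c]; S.wz[c] -= d * S.uz[c];
}

static void half_kick(Sys& S, const Forces& F) {
  const Params& P = S.P;
  double h = 0.5 * P.dt;
  for (int c = 0; c < P.ncarb; ++c) {
    S.wx[c] += h * F.tcx[c] / P.i_c;
    S.wy[c] += h * F.tcy[c] / P.i_c;
    S.wz[c] += h * F.tcz[c] / P.i_c;
    project_w(S, c);
  }
  for (size_t m = 0; m < S.mob.size(); ++m) {
    Mobile& M = S.mob[m];
    double mass = (M.species == 0) ? P.m_k : P.m_w;
    M.vz += h * F.fmz[m] / mass;
    if (M.species == 1) {
      M.om[0] += h * F.twx[m] / P.i_w;
      M.om[1] += h * F.twy[m] / P.i_w;
      M.om[2] += h * F.twz[m] / P.i_w;
    }
  }
}

static void drift(Sys& S) {
  const Params& P = S.P;
  for (int c = 0; c < P.ncarb; ++c) {
    double wn = std::sqrt(S.wx[c] * S.wx[c] + S.wy[c] * S.wy[c] +
                          S.wz[c] * S.wz[c]);
    if (wn > 1e-14) {
      double ax[3] = { S.wx[c] / wn, S.wy[c] / wn, S.wz[c] / wn };
      double u[3] = { S.ux[c], S.uy[c], S.uz[c] };
      rotate3(u, ax, wn * P.dt);
      normalize3(u);
      S.ux[c] = u[0]; S.uy[c] = u[1]; S.uz[c] = u[2];
      project_w(S, c);
    }
  }
  for (Mobile& M : S.mob) {
    M.z += P.dt * M.vz;
    if (M.species == 1) {
      double wn = std::sqrt(M.om[0] * M.om[0] + M.om[1] * M.om[1] +
                            M.om[2] * M.om[2]);
      if (wn > 1e-14) {
        double ax[3] = { M.om[0] / wn, M.om[1] / wn, M.om[2] / wn };
        rotate3(M.d, ax, wn * P.dt);
        rotate3(M.e1, ax, wn * P.dt);
        // re-orthonormalize the frame
        normalize3(M.d);
        double dd = M.e1[0] * M.d[0] + M.e1[1] * M.d[1] + M.e1[2] * M.d[2];
        M.e1[0] -= dd * M.d[0]; M.e1[1] -= dd * M.d[1]; M.e1[2] -= dd * M.d[2];
        normalize3(M.e1);
      }
    }
  }
}

struct EventLog {
  std::vector<double> t;
  std::vector<int> species, type, id, phase;  // type 0 inj, 1 emit, 2 return
  void add(double tt, int sp, int ty, int pid, int ph) {
    t.push_back(tt); species.push_back(sp); type.push_back(ty);
    id.push_back(pid); phase.push_back(ph);
  }
};

// Open boundaries remove and log crossing particles; a closed box instead
// reflects them elastically at the exit and floor planes (used to hold an
// occupancy fixed, e.g. for coordination-mobility windows).
static void apply_boundaries(Sys& S, EventLog& ev, int phase) {
  const Params& P = S.P;
  if (!P.boundaries_on) {
    for (Mobile& M : S.mob) {
      if (M.z > P.z_exit) { M.z = 2 * P.z_exit - M.z; M.vz = -M.vz; }
      else if (M.z < P.z_floor) { M.z = 2 * P.z_floor - M.z; M.vz = -M.vz; }
    }
    return;
  }
  for (size_t m = 0; m < S.mob.size();) {
    if (S.mob[m].z > P.z_exit) {
      ev.add(S.t, S.mob[m].species, 1, S.mob[m].id, phase);
      S.mob.erase(S.mob.begin() + m);
    } else if (S.mob[m].z < P.z_floor) {
      ev.add(S.t, S.mob[m].species, 2, S.mob[m].id, phase);
      S.mob.erase(S.mob.begin() + m);
    } else {
      ++m;
    }
  }
}

static void thermostat(Sys& S) {
  const Params& P = S.P;
  if (P.thermo_prob <= 0.0) return;
  double sg = std::sqrt(P.kt / P.i_c);
  for (int c = 0; c < P.ncarb; ++c) {
    if (S.rng.unif() < P.thermo_prob) {
      S.wx[c] = sg * S.rng.gauss();
      S.wy[c] = sg * S.rng.gauss();
      S.wz[c] = sg * S.rng.gauss();
      project_w(S, c);
    }
  }
}

// returns true if a particle was inserted
static bool try_inject(Sys& S, EventLog& ev, int phase, long long* attempts) {
  const Params& P = S.P;
  ++(*attempts);
  for (const Mobile& M : S.mob)
    if (std::fabs(M.z - P.z_cav) < P.clearance) return false;
  Mobile M;
  M.species = (S.rng.unif() < 0.5) ? 0 : 1;
  M.z = P.z_cav;
  double mass = (M.species == 0) ? P.m_k : P.m_w;
  M.vz = std::sqrt(P.kt / mass) * S.rng.gauss();
  M.id = S.next_id++;
  if (M.species == 1) {
    double up = (S.rng.unif() < 0.5) ? 1.0 : -1.0;
    M.d[0] = 0; M.d[1] = 0; M.d[2] = up;
    double phi = 6.283185307179586 * S.rng.unif();
    M.e1[0] = std::cos(phi); M.e1[1] = std::sin(phi); M.e1[2] = 0;
    double sg = std::sqrt(P.kt / P.i_w);
    M.om[0] = sg * S.rng.gauss();
    M.om[1] = sg * S.rng.gauss();
    M.om[2] = sg * S.rng.gauss();
  } else {
    for (int k = 0; k < 3; ++k) { M.d[k] = 0; M.e1[k] = 0; M.om[k] = 0; }
    M.d[2] = 1; M.e1[0] = 1;
  }
  // insert preserving ascending-z order
  size_t pos = 0;
  while (pos < S.mob.size() && S.mob[pos].z < M.z) ++pos;
  S.mob.insert(S.mob.begin() + pos, M);
  ev.add(S.t, M.species, 0, M.id, phase);
  return true;
}

static void check_order(Sys& S) {
  bool bad = false;
  for (size_t m = 1; m < S.mob.size(); ++m)
    if (S.mob[m].z < S.mob[m - 1].z) { bad = true; break; }
  if (bad) {
    ++S.order_violations;
    std::sort(S.mob.begin(), S.mob.end(),
              [](const Mobile& a, const Mobile& b) { return a.z < b.z; });
  }
}

// --------------------------------------------------------- state export ---
static List export_state(const Sys& S) {
  const Params& P = S.P;
  int n = P.ncarb, nm = (int)S.mob.size();
  NumericMatrix u(n, 3), w(n, 3);
  for (int i = 0; i < n; ++i) {
    u(i, 0) = S.ux[i]; u(i, 1) = S.uy[i]; u(i, 2) = S.uz[i];
    w(i, 0) = S.wx[i]; w(i, 1) = S.wy[i]; w(i, 2) = S.wz[i];
  }
  IntegerVector sp(nm), id(nm);
  NumericVector z(nm), vz(nm);
  NumericMatrix d(nm, 3), e1(nm, 3), om(nm, 3);
  for (int i = 0; i < nm; ++i) {
    sp[i] = S.mob[i].species; id[i] = S.mob[i].id;
    z[i] = S.mob[i].z; vz[i] = S.mob[i].vz;
    for (int k = 0; k < 3; ++k) {
      d(i, k) = S.mob[i].d[k]; e1(i, k) = S.mob[i].e1[k];
      om(i, k) = S.mob[i].om[k];
    }
  }
  return List::create(_["u"] = u, _["w"] = w, _["mob_species"] = sp,
                      _["mob_z"] = z, _["mob_vz"] = vz, _["mob_id"] = id,
                      _["mob_d"] = d, _["mob_e1"] = e1, _["mob_om"] = om,
                      _["t"] = S.t);
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
List cpp_run_md(List params, List state) {
  Params P = parse_params(params);
  Sys S(P.seed);
  S.P = P;
  load_state(S, state);
  S.e_cc = carbon_carbon_energy(P);

  EventLog ev;
  Forces F;
  compute_forces(S, F);

  long long n_total = P.n_therm + P.n_prod;
  // oxygen-position recording (production phase only)
  long long n_rec = 0;
  if (!P.rec_idx.empty() && P.rec_stride > 0)
    n_rec = (P.n_prod + P.rec_stride - 1) / P.rec_stride;
  NumericMatrix oxy(n_rec > 0 ? (int)n_rec : 0, 3 * (int)P.rec_idx.size());
  long long rec_at = 0;
  // energy trace: one record every stride during the run, plus the final state
  long long n_en = 0;
  if (P.energy_stride > 0 && n_total > 0)
    n_en = (n_total - 1) / P.energy_stride + 2;
  NumericMatrix entr(n_en > 0 ? (int)n_en : 0, 6);
  long long en_at = 0;
  // snapshots
  std::vector<List> snaps;
  std::vector<double> snap_t;

  long long inj_attempts = 0, inj_success = 0;
  double next_attempt = (P.injection_on && P.inj_rate > 0)
                          ? S.t - std::log(1.0 - S.rng.unif()) / P.inj_rate
                          : HUGE_VAL;
  int n_init = (int)S.mob.size();

  for (long long step = 0; step < n_total; ++step) {
    bool prod = step >= P.n_therm;
    int phase = prod ? 1 : 0;
    // records taken at the configured stride, at the top of the step
    if (prod) {
      long long ps = step - P.n_therm;
      if (n_rec > 0 && ps % P.rec_stride == 0 && rec_at < n_rec) {
        for (size_t k = 0; k < P.rec_idx.size(); ++k) {
          int c = P.rec_idx[k];
          oxy(rec_at, 3 * k + 0) = P.cx[c] + P.r_co * S.ux[c];
          oxy(rec_at, 3 * k + 1) = P.cy[c] + P.r_co * S.uy[c];
          oxy(rec_at, 3 * k + 2) = P.cz[c] + P.r_co * S.uz[c];
        }
        ++rec_at;
      }
      if (P.snap_stride > 0 && ps % P.snap_stride == 0) {
        snaps.push_back(export_state(S));
        snap_t.push_back(S.t);
      }
    }
    if (n_en > 0 && step % P.energy_stride == 0 && en_at < n_en) {
      double kt_, kr_;
      kinetic_mob(S, &kt_, &kr_);
      entr(en_at, 0) = S.t;
      entr(en_at, 1) = kinetic_carb(S);
      entr(en_at, 2) = kt_;
      entr(en_at, 3) = kr_;
      entr(en_at, 4) = F.pe;
      entr(en_at, 5) = (double)S.mob.size();
      ++en_at;
    }

    half_kick(S, F);
    drift(S);
    check_order(S);
    apply_boundaries(S, ev, phase);
    compute_forces(S, F);
    half_kick(S, F);
    thermostat(S);
    S.t += P.dt;
    if (P.injection_on) {
      bool added = false;
      while (S.t >= next_attempt) {
        if (try_inject(S, ev, phase, &inj_attempts)) {
          ++inj_success;
          added = true;
        }
        next_attempt -= std::log(1.0 - S.rng.unif()) / P.inj_rate;
      }
      if (added) compute_forces(S, F);
    }
    if ((step & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (n_en > 0 && en_at < n_en) {
    double kt_, kr_;
    kinetic_mob(S, &kt_, &kr_);
    entr(en_at, 0) = S.t;
    entr(en_at, 1) = kinetic_carb(S);
    entr(en_at, 2) = kt_;
    entr(en_at, 3) = kr_;
    entr(en_at, 4) = F.pe;
    entr(en_at, 5) = (double)S.mob.size();
    ++en_at;
  }

  DataFrame events = DataFrame::create(
      _["time_fs"] = NumericVector(ev.t.begin(), ev.t.end()),
      _["species"] = IntegerVector(ev.species.begin(), ev.species.end()),
      _["event"] = IntegerVector(ev.type.begin(), ev.type.end()),
      _["particle_id"] = IntegerVector(ev.id.begin(), ev.id.end()),
      _["phase"] = IntegerVector(ev.phase.begin(), ev.phase.end()));
  List snl(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snl[i] = snaps[i];
  return List::create(
      _["events"] = events, _["oxygen"] = oxy, _["energy"] = entr,
      _["snapshots"] = snl,
      _["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end()),
      _["final_state"] = export_state(S),
      _["diagnostics"] = List::create(
          _["order_violations"] = (double)S.order_violations,
          _["injection_attempts"] = (double)inj_attempts,
          _["injections"] = (double)inj_success,
          _["n_initial"] = n_init,
          _["n_final"] = (int)S.mob.size(),
          _["e_cc"] = S.e_cc));
}

// Single-point evaluation of the potential energy and its components.
// [[Rcpp::export]]
List cpp_energy(List params, List state) {
  Params P = parse_params(params);
  Sys S(P.seed);
  S.P = P;
  load_state(S, state);
  S.e_cc = carbon_carbon_energy(P);
  Forces F;
  compute_forces(S, F);
  double kt_, kr_;
  kinetic_mob(S, &kt_, &kr_);
  double kec = kinetic_carb(S);
  return List::create(
      _["potential"] = F.pe, _["coulomb"] = F.pe_coul,
      _["repulsion"] = F.pe_rep, _["bending"] = F.pe_bend,
      _["field"] = F.pe_field, _["kinetic"] = kec + kt_ + kr_,
      _["kinetic_carbonyl"] = kec, _["kinetic_translation"] = kt_,
      _["kinetic_rotation"] = kr_, _["total"] = F.pe + kec + kt_ + kr_);
}

// Single-point evaluation of forces and torques (for oracle tests).
// [[Rcpp::export]]
List cpp_forces(List params, List state) {
  Params P = parse_params(params);
  Sys S(P.seed);
  S.P = P;
  load_state(S, state);
  S.e_cc = carbon_carbon_energy(P);
  Forces F;
  compute_forces(S, F);
  int n = P.ncarb, nm = (int)S.mob.size();
  NumericMatrix tq(n, 3), f3(nm, 3), tw(nm, 3);
  NumericVector fz(nm);
  for (int c = 0; c < n; ++c) {
    tq(c, 0) = F.tcx[c]; tq(c, 1) = F.tcy[c]; tq(c, 2) = F.tcz[c];
  }
  for (int m = 0; m < nm; ++m) {
    fz[m] = F.fmz[m];
    f3(m, 0) = F.fm3x[m]; f3(m, 1) = F.fm3y[m]; f3(m, 2) = F.fm3z[m];
    tw(m, 0) = F.twx[m]; tw(m, 1) = F.twy[m]; tw(m, 2) = F.twz[m];
  }
  return List::create(_["carbonyl_torque"] = tq, _["mobile_fz"] = fz,
                      _["mobile_f3"] = f3, _["water_torque"] = tw,
                      _["potential"] = F.pe);
}
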