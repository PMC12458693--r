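#ifndef WATNET_H
#define WATNET_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Units throughout: Angstrom, kcal/mol, elementary charges.
// Coulomb prefactor and beta arrive from R inside EnergyParams.

static const double WATNET_INF = std::numeric_limits<double>::infinity();
static const double WATNET_R2MIN = 1e-18; // squared distance treated as overlap

struct EnergyParams {
  double cutoff;     // A
  double sw_width;   // A
  double coul;       // kcal A / (mol e^2)
  double beta;       // 1/(kcal/mol)
};

struct Region {
  double c[3];       // droplet centre
  double R;          // droplet radius
  double k;          // half-harmonic force constant
  double lo[3], hi[3]; // gcmc box corners
  bool in_box(const double *o) const {
    return o[0] >= lo[0] && o[0] <= hi[0] &&
           o[1] >= lo[1] && o[1] <= hi[1] &&
           o[2] >= lo[2] && o[2] <= hi[2];
  }
};

struct WaterModelC {
  int m;                       // number of sites (oxygen first)
  std::vector<double> off;     // 3*m molecular-frame offsets (row-major xyz)
  std::vector<double> q;       // per-site charges
  double osig, oeps;           // LJ on the oxygen site only
};

struct HostC {
  int n;
  std::vector<double> x, y, z, sig, eps, q;
};

struct WaterC {
  double o[3];
  double quat[4];              // (w, x, y, z)
  std::vector<double> s;       // 3*m lab-frame site coords
  bool region;
};

inline void quat_to_mat(const double *q, double *Rm) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  Rm[0] = 1 - 2 * (y * y + z * z); Rm[1] = 2 * (x * y - w * z); Rm[2] = 2 * (x * z + w * y);
  Rm[3] = 2 * (x * y + w * z); Rm[4] = 1 - 2 * (x * x + z * z); Rm[5] = 2 * (y * z - w * x);
  Rm[6] = 2 * (x * z - w * y); Rm[7] = 2 * (y * z + w * x); Rm[8] = 1 - 2 * (x * x + y * y);
}

inline void place_sites(const WaterModelC &mod, WaterC &w) {
  double Rm[9];
  quat_to_mat(w.quat, Rm);
  w.s.resize(3 * mod.m);
  for (int s = 0; s < mod.m; ++s) {
    const double *v = &mod.off[3 * s];
    w.s[3 * s + 0] = w.o[0] + Rm[0] * v[0] + Rm[1] * v[1] + Rm[2] * v[2];
    w.s[3 * s + 1] = w.o[1] + Rm[3] * v[0] + Rm[4] * v[1] + Rm[5] * v[2];
    w.s[3 * s + 2] = w.o[2] + Rm[6] * v[0] + Rm[7] * v[1] + Rm[8] * v[2];
  }
}

inline double dist2(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// CHARMM-style energy switching function, C1 at both joins.
inline double switch_factor(double r, const EnergyParams &p) {
  double rc = p.cutoff, ron = p.cutoff - p.sw_width;
  if (r <= ron) return 1.0;
  if (r >= rc) return 0.0;
  double rc2 = rc * rc, ron2 = ron * ron, r2 = r * r;
  double num = (rc2 - r2) * (rc2 - r2) * (rc2 + 2 * r2 - 3 * ron2);
  double den = (rc2 - ron2) * (rc2 - ron2) * (rc2 - ron2);
  return num / den;
}

inline double lj_energy(double r2, double sig, double eps) {
  if (eps <= 0.0 || sig <= 0.0) return 0.0;
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  return 4.0 * eps * s6 * (s6 - 1.0);
}

// host site j vs whole water molecule; molecule-based switching on the
// oxygen--site distance so a water's sites switch off together.
inline double host_site_water_energy(const HostC &h, int j, const WaterC &w,
                                     const WaterModelC &mod, const EnergyParams &p) {
  double hx[3] = { h.x[j], h.y[j], h.z[j] };
  double r2o = dist2(hx, w.o);
  if (r2o >= p.cutoff * p.cutoff) return 0.0;
  if (r2o < WATNET_R2MIN) return WATNET_INF;
  double e = lj_energy(r2o, 0.5 * (h.sig[j] + mod.osig), std::sqrt(h.eps[j] * mod.oeps));
  if (h.q[j] != 0.0) {
    for (int s = 0; s < mod.m; ++s) {
      if (mod.q[s] == 0.0) continue;
      double r2 = dist2(hx, &w.s[3 * s]);
      if (r2 < WATNET_R2MIN) return WATNET_INF;
      e += p.coul * h.q[j] * mod.q[s] / std::sqrt(r2);
    }
  }
  return e * switch_factor(std::sqrt(r2o), p);
}

inline double host_water_energy(const HostC &h, const WaterC &w,
                                const WaterModelC &mod, const EnergyParams &p) {
  double e = 0.0;
  for (int j = 0; j < h.n; ++j) {
    double ej = host_site_water_energy(h, j, w, mod, p);
    if (ej == WATNET_INF) return WATNET_INF;
    e += ej;
  }
  return e;
}

// water-water: switching on the O-O distance for the whole molecule pair.
inline double water_water_energy(const WaterC &a, const WaterC &b,
                                 const WaterModelC &mod, const EnergyParams &p) {
  double r2o = dist2(a.o, b.o);
  if (r2o >= p.cutoff * p.cutoff) return 0.0;
  if (r2o < WATNET_R2MIN) return WATNET_INF;
  double e = lj_energy(r2o, mod.osig, mod.oeps);
  for (int s = 0; s < mod.m; ++s) {
    if (mod.q[s] == 0.0) continue;
    for (int t = 0; t < mod.m; ++t) {
      if (mod.q[t] == 0.0) continue;
      double r2 = dist2(&a.s[3 * s], &b.s[3 * t]);
      if (r2 < WATNET_R2MIN) return WATNET_INF;
      e += p.coul * mod.q[s] * mod.q[t] / std::sqrt(r2);
    }
  }
  return e * switch_factor(std::sqrt(r2o), p);
}

inline double restraint_energy_c(const double *o, const Region &reg) {
  double d = std::sqrt(dist2(o, reg.c));
  if (d <= reg.R) return 0.0;
  double x = d - reg.R;
  return 0.5 * reg.k * x * x;
}

// ---- softcore forms (dual-topology alchemistry) ----
// LJ:      4 eps w [ A^-2 - A^-1 ],  A = delta (1-w) + (r/sig)^6
// Coulomb: C qq w / sqrt(delta_c (1-w) + r^2)
// Both reduce to the plain potentials at w = 1 and vanish at w = 0;
// finite at r = 0 for w < 1.
inline double softcore_lj(double r2, double sig, double eps, double w, double delta) {
  if (eps <= 0.0 || sig <= 0.0 || w <= 0.0) return 0.0;
  double s6 = (r2 / (sig * sig));
  s6 = s6 * s6 * s6; // (r/sig)^6
  double A = delta * (1.0 - w) + s6;
  if (A <= 0.0) return WATNET_INF;
  return 4.0 * eps * w * (1.0 / (A * A) - 1.0 / A);
}

inline double softcore_coul(double r2, double qq, double w, double delta_c,
                            const EnergyParams &p) {
  if (qq == 0.0 || w <= 0.0) return 0.0;
  double D = delta_c * (1.0 - w) + r2;
  if (D <= 0.0) return WATNET_INF;
  return p.coul * qq * w / std::sqrt(D);
}

// ---- converters from R objects ----
inline EnergyParams params_from_r(const Rcpp::NumericVector &v) {
  EnergyParams p;
  p.cutoff = v["cutoff"]; p.sw_width = v["switch_width"];
  p.coul = v["coulomb"]; p.beta = v["beta"];
  return p;
}

inline Region region_from_r(const Rcpp::NumericVector &v) {
  Region r;
  r.c[0] = v[0]; r.c[1] = v[1]; r.c[2] = v[2];
  r.R = v[3]; r.k = v[4];
  for (int i = 0; i < 3; ++i) { r.lo[i] = v[5 + i]; r.hi[i] = v[8 + i]; }
  return r;
}

inline WaterModelC model_from_r(const Rcpp::List &m) {
  WaterModelC w;
  Rcpp::NumericMatrix off = m["site_offsets"];
  Rcpp::NumericVector q = m["site_charges"];
  w.m = off.nrow();
  w.off.resize(3 * w.m);
  for (int i = 0; i < w.m; ++i)
    for (int j = 0; j < 3; ++j) w.off[3 * i + j] = off(i, j);
  w.q.assign(q.begin(), q.end());
  w.osig = Rcpp::as<double>(m["oxygen_lj_sigma"]);
  w.oeps = Rcpp::as<double>(m["oxygen_lj_epsilon"]);
  return w;
}

inline HostC host_from_r(const Rcpp::NumericMatrix &h) {
  HostC out;
  out.n = h.nrow();
  out.x.resize(out.n); out.y.resize(out.n); out.z.resize(out.n);
  out.sig.resize(out.n); out.eps.resize(out.n); out.q.resize(out.n);
  for (int i = 0; i < out.n; ++i) {
    out.x[i] = h(i, 0); out.y[i] = h(i, 1); out.z[i] = h(i, 2);
    out.sig[i] = h(i, 3); out.eps[i] = h(i, 4); out.q[i] = h(i, 5);
  }
  return out;
}

inline std::vector<WaterC> waters_from_r(const Rcpp::NumericMatrix &w,
                                         const WaterModelC &mod, const Region &reg) {
  std::vector<WaterC> out(w.nrow());
  for (int i = 0; i < w.nrow(); ++i) {
    WaterC &wi = out[i];
    wi.o[0] = w(i, 0); wi.o[1] = w(i, 1); wi.o[2] = w(i, 2);
    for (int j = 0; j < 4; ++j) wi.quat[j] = w(i, 3 + j);
    place_sites(mod, wi);
    wi.region = reg.in_box(wi.o);
  }
  return out;
}

inline Rcpp::NumericMatrix waters_to_r(const std::vector<WaterC> &w) {
  Rcpp::NumericMatrix out(w.size(), 7);
  for (size_t i = 0; i < w.size(); ++i) {
    out(i, 0) = w[i].o[0]; out(i, 1) = w[i].o[1]; out(i, 2) = w[i].o[2];
    for (int j = 0; j < 4; ++j) out(i, 3 + j) = w[i].quat[j];
  }
  return out;
}

#endif
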