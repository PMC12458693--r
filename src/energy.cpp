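#include "watnet.h"
#include "rng.h"
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_switching_factor(double r, NumericVector params) {
  EnergyParams p = params_from_r(params);
  return switch_factor(r, p);
}

// Plain single-site pair energy with Lorentz-Berthelot combination and
// molecule-free switching on the site-site distance.
// [[Rcpp::export]]
double cpp_pair_energy(NumericVector a, NumericVector b, NumericVector params) {
  // a, b: (x, y, z, sigma, epsilon, charge)
  EnergyParams p = params_from_r(params);
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 < WATNET_R2MIN) stop("pair_energy: zero distance (overlapping sites)");
  if (r2 >= p.cutoff * p.cutoff) return 0.0;
  double r = std::sqrt(r2);
  double e = lj_energy(r2, 0.5 * (a[3] + b[3]), std::sqrt(a[4] * b[4]));
  e += p.coul * a[5] * b[5] / r;
  return e * switch_factor(r, p);
}

// [[Rcpp::export]]
double cpp_softcore_pair_energy(NumericVector a, NumericVector b,
                                double lambda_scale, double sc_delta,
                                double sc_delta_c, NumericVector params) {
  EnergyParams p = params_from_r(params);
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= p.cutoff * p.cutoff) return 0.0;
  double e = softcore_lj(r2, 0.5 * (a[3] + b[3]), std::sqrt(a[4] * b[4]),
                         lambda_scale, sc_delta);
  e += softcore_coul(r2, a[5] * b[5], lambda_scale, sc_delta_c, p);
  return e * switch_factor(std::sqrt(r2), p);
}

// [[Rcpp::export]]
NumericMatrix cpp_water_sites(NumericVector oxygen, NumericVector quat, List model) {
  WaterModelC mod = model_from_r(model);
  WaterC w;
  w.o[0] = oxygen[0]; w.o[1] = oxygen[1]; w.o[2] = oxygen[2];
  for (int j = 0; j < 4; ++j) w.quat[j] = quat[j];
  place_sites(mod, w);
  NumericMatrix out(mod.m, 3);
  for (int s = 0; s < mod.m; ++s)
    for (int j = 0; j < 3; ++j) out(s, j) = w.s[3 * s + j];
  return out;
}

// [[Rcpp::export]]
double cpp_host_water_energy(NumericMatrix host, NumericVector oxygen,
                             NumericVector quat, List model, NumericVector params) {
  EnergyParams p = params_from_r(params);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  WaterC w;
  w.o[0] = oxygen[0]; w.o[1] = oxygen[1]; w.o[2] = oxygen[2];
  for (int j = 0; j < 4; ++j) w.quat[j] = quat[j];
  place_sites(mod, w);
  return host_water_energy(h, w, mod, p);
}

// [[Rcpp::export]]
double cpp_water_water_energy(NumericVector o1, NumericVector q1,
                              NumericVector o2, NumericVector q2,
                              List model, NumericVector params) {
  EnergyParams p = params_from_r(params);
  WaterModelC mod = model_from_r(model);
  WaterC a, b;
  for (int j = 0; j < 3; ++j) { a.o[j] = o1[j]; b.o[j] = o2[j]; }
  for (int j = 0; j < 4; ++j) { a.quat[j] = q1[j]; b.quat[j] = q2[j]; }
  place_sites(mod, a); place_sites(mod, b);
  return water_water_energy(a, b, mod, p);
}

// Full potential: host-water + unique water-water pairs + droplet restraints.
// Host-host terms are constant for a rigid host and excluded.
// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix host, NumericMatrix waters, List model,
                        NumericVector params, NumericVector region) {
  EnergyParams p = params_from_r(params);
  Region reg = region_from_r(region);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  std::vector<WaterC> w = waters_from_r(waters, mod, reg);
  double e = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    double ei = host_water_energy(h, w[i], mod, p);
    if (ei == WATNET_INF) return WATNET_INF;
    e += ei + restraint_energy_c(w[i].o, reg);
    for (size_t j = i + 1; j < w.size(); ++j) {
      double eij = water_water_energy(w[i], w[j], mod, p);
      if (eij == WATNET_INF) return WATNET_INF;
      e += eij;
    }
  }
  return e;
}

// ---- RNG plumbing ----

// [[Rcpp::export]]
RawVector cpp_rng_create(double seed, double stream) {
  Xoshiro g;
  g.seed((uint64_t)seed, (uint64_t)stream);
  RawVector rv(32);
  g.to_raw(rv);
  return rv;
}

// [[Rcpp::export]]
List cpp_rng_runif(RawVector state, int n) {
  Xoshiro g;
  g.from_raw(state);
  NumericVector u(n);
  for (int i = 0; i < n; ++i) u[i] = g.runif();
  RawVector rv(32);
  g.to_raw(rv);
  return List::create(_["u"] = u, _["state"] = rv);
}
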