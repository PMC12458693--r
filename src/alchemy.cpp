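#include "watnet.h"
#include "mc.h"
using namespace Rcpp;

struct LigSite { double x[3]; double sig, eps, q; };

// lab-frame ligand sites from molecular-frame sites (centred on the centre
// of geometry) and a rigid-body pose (position + quaternion)
static std::vector<LigSite> lig_lab(const NumericMatrix &lig, const double *pose) {
  double Rm[9];
  quat_to_mat(pose + 3, Rm);
  std::vector<LigSite> out(lig.nrow());
  for (int i = 0; i < lig.nrow(); ++i) {
    double v[3] = { lig(i, 0), lig(i, 1), lig(i, 2) };
    out[i].x[0] = pose[0] + Rm[0] * v[0] + Rm[1] * v[1] + Rm[2] * v[2];
    out[i].x[1] = pose[1] + Rm[3] * v[0] + Rm[4] * v[1] + Rm[5] * v[2];
    out[i].x[2] = pose[2] + Rm[6] * v[0] + Rm[7] * v[1] + Rm[8] * v[2];
    out[i].sig = lig(i, 3); out[i].eps = lig(i, 4); out[i].q = lig(i, 5);
  }
  return out;
}

// softcore interaction of one ligand site with one host site
static double lig_host_site(const LigSite &l, const HostC &h, int j, double w,
                            double sc_d, double sc_dc, const EnergyParams &p) {
  double hx[3] = { h.x[j], h.y[j], h.z[j] };
  double r2 = dist2(l.x, hx);
  if (r2 >= p.cutoff * p.cutoff) return 0.0;
  double e = softcore_lj(r2, 0.5 * (l.sig + h.sig[j]), std::sqrt(l.eps * h.eps[j]), w, sc_d);
  e += softcore_coul(r2, l.q * h.q[j], w, sc_dc, p);
  return e * switch_factor(std::sqrt(r2), p);
}

// softcore interaction of one ligand site with one whole water
// (molecule-based switching on the site-oxygen distance)
static double lig_water_site(const LigSite &l, const WaterC &wat,
                             const WaterModelC &mod, double w,
                             double sc_d, double sc_dc, const EnergyParams &p) {
  double r2o = dist2(l.x, wat.o);
  if (r2o >= p.cutoff * p.cutoff) return 0.0;
  double e = softcore_lj(r2o, 0.5 * (l.sig + mod.osig), std::sqrt(l.eps * mod.oeps), w, sc_d);
  if (l.q != 0.0) {
    for (int s = 0; s < mod.m; ++s) {
      if (mod.q[s] == 0.0) continue;
      double r2 = dist2(l.x, &wat.s[3 * s]);
      e += softcore_coul(r2, l.q * mod.q[s], w, sc_dc, p);
    }
  }
  return e * switch_factor(std::sqrt(r2o), p);
}

static double lig_env_energy(const std::vector<LigSite> &lig, const HostC &h,
                             const std::vector<WaterC> &wat, const WaterModelC &mod,
                             double w, double sc_d, double sc_dc, const EnergyParams &p) {
  if (w <= 0.0) return 0.0;
  double e = 0.0;
  for (const auto &l : lig) {
    for (int j = 0; j < h.n; ++j) e += lig_host_site(l, h, j, w, sc_d, sc_dc, p);
    for (const auto &wm : wat) e += lig_water_site(l, wm, mod, w, sc_d, sc_dc, p);
  }
  return e;
}

static double lig_one_water(const std::vector<LigSite> &lig, const WaterC &wat,
                            const WaterModelC &mod, double w,
                            double sc_d, double sc_dc, const EnergyParams &p) {
  if (w <= 0.0) return 0.0;
  double e = 0.0;
  for (const auto &l : lig) e += lig_water_site(l, wat, mod, w, sc_d, sc_dc, p);
  return e;
}

static double dummy_bond(const double *poseA, const double *poseB, double k) {
  double d2 = (poseA[0] - poseB[0]) * (poseA[0] - poseB[0]) +
              (poseA[1] - poseB[1]) * (poseA[1] - poseB[1]) +
              (poseA[2] - poseB[2]) * (poseA[2] - poseB[2]);
  return 0.5 * k * d2;
}

// flat-bottom harmonic keeping each ligand copy's centre of geometry near a
// reference point (prevents a weakly coupled pair drifting out of the site);
// rest = (cx, cy, cz, k, radius); lambda-independent
static double cog_restraint(const double *pose, const double *rest) {
  if (rest[3] <= 0.0) return 0.0;
  double dx = pose[0] - rest[0], dy = pose[1] - rest[1], dz = pose[2] - rest[2];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (d <= rest[4]) return 0.0;
  double x = d - rest[4];
  return 0.5 * rest[3] * x * x;
}

// lambda-dependent part of the dual-topology potential (plus the dummy bond):
// environment--B weighted by lambda, environment--A by (1 - lambda),
// A--B cross interactions excluded (both rigid).
static double lambda_part(const std::vector<LigSite> &A, const std::vector<LigSite> &Bl,
                          const HostC &h, const std::vector<WaterC> &wat,
                          const WaterModelC &mod, double lambda, double sc_d,
                          double sc_dc, double dummy_k, const double *poseA,
                          const double *poseB, const double *lig_rest,
                          const EnergyParams &p) {
  return lig_env_energy(A, h, wat, mod, 1.0 - lambda, sc_d, sc_dc, p) +
         lig_env_energy(Bl, h, wat, mod, lambda, sc_d, sc_dc, p) +
         dummy_bond(poseA, poseB, dummy_k) +
         cog_restraint(poseA, lig_rest) + cog_restraint(poseB, lig_rest);
}

// Full dual-topology potential at one lambda (environment terms included).
// [[Rcpp::export]]
double cpp_dual_topology_energy(NumericMatrix host, List model, NumericVector params,
                                NumericVector region, NumericMatrix waters,
                                NumericMatrix ligA, NumericMatrix ligB,
                                NumericVector poseA, NumericVector poseB,
                                double lambda, double sc_delta, double sc_delta_c,
                                double dummy_k, NumericVector lig_restraint) {
  EnergyParams p = params_from_r(params);
  Region reg = region_from_r(region);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  std::vector<WaterC> wat = waters_from_r(waters, mod, reg);
  double e = 0.0;
  for (size_t i = 0; i < wat.size(); ++i) {
    e += host_water_energy(h, wat[i], mod, p) + restraint_energy_c(wat[i].o, reg);
    for (size_t j = i + 1; j < wat.size(); ++j)
      e += water_water_energy(wat[i], wat[j], mod, p);
  }
  std::vector<LigSite> A = lig_lab(ligA, &poseA[0]), Bl = lig_lab(ligB, &poseB[0]);
  e += lambda_part(A, Bl, h, wat, mod, lambda, sc_delta, sc_delta_c, dummy_k,
                   &poseA[0], &poseB[0], &lig_restraint[0], p);
  return e;
}

// Reduced potentials of the current configuration at a set of lambdas
// (lambda-dependent part only; lambda-independent terms cancel in MBAR
// and in replica-exchange differences).
// [[Rcpp::export]]
NumericVector cpp_alch_reduced(NumericMatrix host, List model, NumericVector params,
                               NumericVector region, NumericMatrix waters,
                               NumericMatrix ligA, NumericMatrix ligB,
                               NumericVector poseA, NumericVector poseB,
                               NumericVector lambdas, double sc_delta,
                               double sc_delta_c, double dummy_k,
                               NumericVector lig_restraint) {
  EnergyParams p = params_from_r(params);
  Region reg = region_from_r(region);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  std::vector<WaterC> wat = waters_from_r(waters, mod, reg);
  std::vector<LigSite> A = lig_lab(ligA, &poseA[0]), Bl = lig_lab(ligB, &poseB[0]);
  NumericVector out(lambdas.size());
  for (int k = 0; k < lambdas.size(); ++k)
    out[k] = p.beta * lambda_part(A, Bl, h, wat, mod, lambdas[k], sc_delta,
                                  sc_delta_c, dummy_k, &poseA[0], &poseB[0],
                                  &lig_restraint[0], p);
  return out;
}

// One chunk of canonical sampling at a fixed lambda window.
// move_probs: c(water displacement, coupled ligand rigid-body move).
// Waters keep their region-box membership (fixed-N leg); ligand moves apply
// the same translation to both copies and the same rotation about each
// centre of geometry, so the dummy bond length is preserved.
// [[Rcpp::export]]
List cpp_alch_chunk(NumericMatrix host, List model, NumericVector params,
                    NumericVector region, NumericMatrix waters_in,
                    NumericMatrix ligA, NumericMatrix ligB,
                    NumericVector poseA_in, NumericVector poseB_in,
                    double lambda_sim, NumericVector lambda_eval,
                    double sc_delta, double sc_delta_c, double dummy_k,
                    NumericVector lig_restraint, NumericVector move_probs,
                    double max_translate,
                    double max_rotate, double lig_max_translate,
                    double lig_max_rotate, int n_moves, int sample_interval,
                    RawVector rng_state) {
  EnergyParams p = params_from_r(params);
  Region reg = region_from_r(region);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  std::vector<WaterC> wat = waters_from_r(waters_in, mod, reg);
  double poseA[7], poseB[7];
  for (int j = 0; j < 7; ++j) { poseA[j] = poseA_in[j]; poseB[j] = poseB_in[j]; }
  Xoshiro g;
  g.from_raw(rng_state);

  double wA = 1.0 - lambda_sim, wB = lambda_sim;
  std::vector<LigSite> A = lig_lab(ligA, poseA), Bl = lig_lab(ligB, poseB);

  long att[2] = {0, 0}, acc[2] = {0, 0};
  int n_samples = (sample_interval > 0) ? n_moves / sample_interval : 0;
  NumericMatrix u_kn(n_samples, lambda_eval.size());
  int srow = 0;

  for (int mv = 1; mv <= n_moves; ++mv) {
    double u = g.runif();
    int type = (u <= move_probs[0]) ? 0 : 1;
    ++att[type];

    if (type == 0 && !wat.empty()) {
      int idx = (int)(g.runif() * wat.size());
      if (idx >= (int)wat.size()) idx = (int)wat.size() - 1;
      WaterC trial = wat[idx];
      trial.o[0] += (2.0 * g.runif() - 1.0) * max_translate;
      trial.o[1] += (2.0 * g.runif() - 1.0) * max_translate;
      trial.o[2] += (2.0 * g.runif() - 1.0) * max_translate;
      double nq[4];
      perturb_quat(g, wat[idx].quat, max_rotate, nq);
      for (int j = 0; j < 4; ++j) trial.quat[j] = nq[j];
      place_sites(mod, trial);
      if (reg.in_box(trial.o) == wat[idx].region) {
        double u_old = host_water_energy(h, wat[idx], mod, p) +
                       restraint_energy_c(wat[idx].o, reg) +
                       lig_one_water(A, wat[idx], mod, wA, sc_delta, sc_delta_c, p) +
                       lig_one_water(Bl, wat[idx], mod, wB, sc_delta, sc_delta_c, p);
        double u_new = host_water_energy(h, trial, mod, p) +
                       restraint_energy_c(trial.o, reg) +
                       lig_one_water(A, trial, mod, wA, sc_delta, sc_delta_c, p) +
                       lig_one_water(Bl, trial, mod, wB, sc_delta, sc_delta_c, p);
        for (size_t j = 0; j < wat.size(); ++j) {
          if ((int)j == idx) continue;
          u_old += water_water_energy(wat[idx], wat[j], mod, p);
          u_new += water_water_energy(trial, wat[j], mod, p);
        }
        if (u_new != WATNET_INF &&
            std::log(g.runif()) < -p.beta * (u_new - u_old)) {
          wat[idx] = trial;
          ++acc[0];
        }
      }
    } else if (type == 1) {
      // coupled rigid-body move of both ligand copies
      double dt[3] = { (2.0 * g.runif() - 1.0) * lig_max_translate,
                       (2.0 * g.runif() - 1.0) * lig_max_translate,
                       (2.0 * g.runif() - 1.0) * lig_max_translate };
      double trialA[7], trialB[7];
      for (int j = 0; j < 3; ++j) { trialA[j] = poseA[j] + dt[j]; trialB[j] = poseB[j] + dt[j]; }
      double dq[4], nqA[4], nqB[4];
      make_dq(g, lig_max_rotate, dq); // same random rotation for both copies
      apply_dq(dq, poseA + 3, nqA);
      apply_dq(dq, poseB + 3, nqB);
      for (int j = 0; j < 4; ++j) { trialA[3 + j] = nqA[j]; trialB[3 + j] = nqB[j]; }
      std::vector<LigSite> An = lig_lab(ligA, trialA), Bn = lig_lab(ligB, trialB);
      double u_old = lig_env_energy(A, h, wat, mod, wA, sc_delta, sc_delta_c, p) +
                     lig_env_energy(Bl, h, wat, mod, wB, sc_delta, sc_delta_c, p) +
                     dummy_bond(poseA, poseB, dummy_k) +
                     cog_restraint(poseA, &lig_restraint[0]) +
                     cog_restraint(poseB, &lig_restraint[0]);
      double u_new = lig_env_energy(An, h, wat, mod, wA, sc_delta, sc_delta_c, p) +
                     lig_env_energy(Bn, h, wat, mod, wB, sc_delta, sc_delta_c, p) +
                     dummy_bond(trialA, trialB, dummy_k) +
                     cog_restraint(trialA, &lig_restraint[0]) +
                     cog_restraint(trialB, &lig_restraint[0]);
      if (u_new != WATNET_INF && std::log(g.runif()) < -p.beta * (u_new - u_old)) {
        for (int j = 0; j < 7; ++j) { poseA[j] = trialA[j]; poseB[j] = trialB[j]; }
        A.swap(An); Bl.swap(Bn);
        ++acc[1];
      }
    }

    if (sample_interval > 0 && mv % sample_interval == 0 && srow < n_samples) {
      for (int k = 0; k < lambda_eval.size(); ++k)
        u_kn(srow, k) = p.beta * lambda_part(A, Bl, h, wat, mod, lambda_eval[k],
                                             sc_delta, sc_delta_c, dummy_k,
                                             poseA, poseB, &lig_restraint[0], p);
      ++srow;
    }
  }

  RawVector rv(32);
  g.to_raw(rv);
  return List::create(
    _["waters"] = waters_to_r(wat),
    _["poseA"] = NumericVector(poseA, poseA + 7),
    _["poseB"] = NumericVector(poseB, poseB + 7),
    _["u_kn"] = u_kn,
    _["rng_state"] = rv,
    _["attempted"] = NumericVector(att, att + 2),
    _["accepted"] = NumericVector(acc, acc + 2));
}
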