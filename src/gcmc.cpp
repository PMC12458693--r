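#include "watnet.h"
#include "mc.h"
using namespace Rcpp;

// Interaction energy of water i with host, all other waters, and restraint.
static double one_water_energy(const HostC &h, const std::vector<WaterC> &w,
                               const WaterC &wi, int skip,
                               const WaterModelC &mod, const EnergyParams &p,
                               const Region &reg) {
  double e = host_water_energy(h, wi, mod, p);
  if (e == WATNET_INF) return WATNET_INF;
  for (int j = 0; j < (int)w.size(); ++j) {
    if (j == skip) continue;
    double ej = water_water_energy(wi, w[j], mod, p);
    if (ej == WATNET_INF) return WATNET_INF;
    e += ej;
  }
  return e + restraint_energy_c(wi.o, reg);
}

// One chunk of GCMC moves at a single B value.  The R driver composes chunks
// into equilibration phases, production, and replica-exchange sweeps.
// move_probs: c(insert, delete, displace_region, displace_bulk); must sum to 1.
// [[Rcpp::export]]
List cpp_gcmc_chunk(NumericMatrix host, List model, NumericVector params,
                    NumericVector region, NumericMatrix waters_in, double B,
                    NumericVector move_probs, double max_translate,
                    double max_rotate, int n_moves, int sample_interval,
                    bool record_frames, RawVector rng_state, double u_running,
                    bool check_energy) {
  EnergyParams p = params_from_r(params);
  Region reg = region_from_r(region);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  std::vector<WaterC> w = waters_from_r(waters_in, mod, reg);
  Xoshiro g;
  g.from_raw(rng_state);

  double Vbox = (reg.hi[0] - reg.lo[0]) * (reg.hi[1] - reg.lo[1]) * (reg.hi[2] - reg.lo[2]);
  if (Vbox <= 0) stop("GCMC box has non-positive volume");

  int n_region = 0;
  for (auto &wi : w) if (wi.region) ++n_region;

  if (!R_finite(u_running)) {
    // recompute from scratch
    u_running = 0.0;
    for (size_t i = 0; i < w.size(); ++i) {
      u_running += host_water_energy(h, w[i], mod, p) + restraint_energy_c(w[i].o, reg);
      for (size_t j = i + 1; j < w.size(); ++j)
        u_running += water_water_energy(w[i], w[j], mod, p);
    }
  }
  if (!R_finite(u_running)) stop("non-finite total energy in starting configuration");

  double cum[4];
  cum[0] = move_probs[0];
  for (int i = 1; i < 4; ++i) cum[i] = cum[i - 1] + move_probs[i];

  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};
  std::vector<int> sample_N;
  std::vector<double> sample_U;
  std::vector<double> frames; // frame index + oxygen coords of region waters
  double max_drift = 0.0;
  int n_samples = (sample_interval > 0) ? n_moves / sample_interval : 0;
  sample_N.reserve(n_samples); sample_U.reserve(n_samples);

  for (int mv = 1; mv <= n_moves; ++mv) {
    double u = g.runif();
    int type = 0;
    while (type < 3 && u > cum[type]) ++type;
    ++att[type];

    if (type == 0) {
      // insertion into the GCMC box, uniform position and orientation
      WaterC nw;
      nw.o[0] = reg.lo[0] + g.runif() * (reg.hi[0] - reg.lo[0]);
      nw.o[1] = reg.lo[1] + g.runif() * (reg.hi[1] - reg.lo[1]);
      nw.o[2] = reg.lo[2] + g.runif() * (reg.hi[2] - reg.lo[2]);
      random_quat(g, nw.quat);
      place_sites(mod, nw);
      nw.region = true;
      double dU = one_water_energy(h, w, nw, -1, mod, p, reg);
      if (dU != WATNET_INF) {
        double ln_acc = B - std::log((double)(n_region + 1)) - p.beta * dU;
        if (std::log(g.runif()) < ln_acc) {
          w.push_back(nw);
          ++n_region;
          u_running += dU;
          ++acc[0];
        }
      }
    } else if (type == 1) {
      // deletion of a uniformly chosen region water
      if (n_region > 0) {
        int pick = (int)(g.runif() * n_region);
        if (pick >= n_region) pick = n_region - 1;
        int idx = -1, seen = -1;
        for (int i = 0; i < (int)w.size(); ++i) {
          if (w[i].region && ++seen == pick) { idx = i; break; }
        }
        double uw = one_water_energy(h, w, w[idx], idx, mod, p, reg);
        // dU = -uw (remove all its interactions)
        double ln_acc = std::log((double)n_region) - B + p.beta * uw;
        if (std::log(g.runif()) < ln_acc) {
          w[idx] = w.back();
          w.pop_back();
          --n_region;
          u_running -= uw;
          ++acc[1];
        }
      }
    } else {
      // displacement: type 2 -> region water, type 3 -> bulk water
      bool want_region = (type == 2);
      int n_class = want_region ? n_region : (int)w.size() - n_region;
      if (n_class > 0) {
        int pick = (int)(g.runif() * n_class);
        if (pick >= n_class) pick = n_class - 1;
        int idx = -1, seen = -1;
        for (int i = 0; i < (int)w.size(); ++i) {
          if (w[i].region == want_region && ++seen == pick) { idx = i; break; }
        }
        WaterC trial = w[idx];
        trial.o[0] += (2.0 * g.runif() - 1.0) * max_translate;
        trial.o[1] += (2.0 * g.runif() - 1.0) * max_translate;
        trial.o[2] += (2.0 * g.runif() - 1.0) * max_translate;
        double nq[4];
        perturb_quat(g, w[idx].quat, max_rotate, nq);
        for (int j = 0; j < 4; ++j) trial.quat[j] = nq[j];
        place_sites(mod, trial);
        // reject moves that carry an oxygen across the box boundary
        if (reg.in_box(trial.o) == want_region) {
          trial.region = want_region;
          double u_old = one_water_energy(h, w, w[idx], idx, mod, p, reg);
          double u_new = one_water_energy(h, w, trial, idx, mod, p, reg);
          if (u_new != WATNET_INF) {
            double dU = u_new - u_old;
            if (std::log(g.runif()) < -p.beta * dU) {
              w[idx] = trial;
              u_running += dU;
              ++acc[type];
            }
          }
        }
      }
    }

    if (!R_finite(u_running))
      stop("non-finite running energy after move %d", mv);

    if (sample_interval > 0 && mv % sample_interval == 0) {
      sample_N.push_back(n_region);
      sample_U.push_back(u_running);
      if (check_energy) {
        double ufull = 0.0;
        for (size_t i = 0; i < w.size(); ++i) {
          ufull += host_water_energy(h, w[i], mod, p) + restraint_energy_c(w[i].o, reg);
          for (size_t j = i + 1; j < w.size(); ++j)
            ufull += water_water_energy(w[i], w[j], mod, p);
        }
        double d = std::fabs(ufull - u_running);
        if (d > max_drift) max_drift = d;
      }
      if (record_frames) {
        int fidx = (int)sample_N.size();
        for (auto &wi : w) {
          if (!wi.region) continue;
          frames.push_back((double)fidx);
          frames.push_back(wi.o[0]);
          frames.push_back(wi.o[1]);
          frames.push_back(wi.o[2]);
        }
      }
    }
  }

  RawVector rv(32);
  g.to_raw(rv);
  NumericMatrix fr(frames.size() / 4, 4);
  for (int i = 0; i < fr.nrow(); ++i)
    for (int j = 0; j < 4; ++j) fr(i, j) = frames[4 * i + j];
  colnames(fr) = CharacterVector::create("frame", "x", "y", "z");

  return List::create(
    _["waters"] = waters_to_r(w),
    _["rng_state"] = rv,
    _["u_total"] = u_running,
    _["n_region"] = n_region,
    _["sample_N"] = IntegerVector(sample_N.begin(), sample_N.end()),
    _["sample_U"] = NumericVector(sample_U.begin(), sample_U.end()),
    _["frames"] = fr,
    _["attempted"] = NumericVector(att, att + 4),
    _["accepted"] = NumericVector(acc, acc + 4),
    _["max_drift"] = max_drift);
}
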