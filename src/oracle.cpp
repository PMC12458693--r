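#include "watnet.h"
using namespace Rcpp;

// Exact grand-partition reference by Riemann enumeration.
//
// States are (grid point, orientation) pairs with weight w = 1/(P*O) and
// host-interaction Boltzmann factor b.  With the engine's Adams
// normalisation,  Xi(B) = sum_N e^{BN} zeta_N  where  zeta_N is the
// unordered sum over N-subsets of states of  prod(w b) * prod_pairs
// exp(-beta u_ww).  The ideal-gas limit (b = 1, no interactions) gives
// zeta_N -> 1/N!  and <N> = e^B exactly as grid resolution grows.
//
// Enumeration is exact up to N = min(max_n, 3) over a kept state set
// (cumulative Boltzmann weight >= 1 - tail_drop of zeta_1); dropped
// low-weight states re-enter through non-interacting completion terms,
// and N > 3 uses the same completion (documented, refinement-checked).
// [[Rcpp::export]]
List cpp_grid_oracle(NumericMatrix host, List model, NumericVector params,
                     NumericMatrix points, NumericMatrix quats,
                     NumericVector B, int max_n, double tail_drop,
                     double guard_states) {
  EnergyParams p = params_from_r(params);
  WaterModelC mod = model_from_r(model);
  HostC h = host_from_r(host);
  int P = points.nrow(), O = quats.nrow();
  double w0 = 1.0 / ((double)P * (double)O);

  // host Boltzmann factor of every state
  std::vector<double> b((size_t)P * O);
  std::vector<WaterC> state_water;
  double s_total = 0.0;
  {
    WaterC wi;
    for (int i = 0; i < P; ++i) {
      wi.o[0] = points(i, 0); wi.o[1] = points(i, 1); wi.o[2] = points(i, 2);
      for (int o = 0; o < O; ++o) {
        for (int j = 0; j < 4; ++j) wi.quat[j] = quats(o, j);
        place_sites(mod, wi);
        double e = host_water_energy(h, wi, mod, p);
        double bb = (e == WATNET_INF) ? 0.0 : std::exp(-p.beta * e);
        b[(size_t)i * O + o] = bb;
        s_total += w0 * bb;
      }
    }
  }

  // keep the highest-weight states covering (1 - tail_drop) of zeta_1
  std::vector<size_t> ord(b.size());
  for (size_t i = 0; i < b.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t c) { return b[a] > b[c]; });
  double target = (1.0 - tail_drop) * s_total;
  double s_kept = 0.0;
  size_t K = 0;
  while (K < ord.size() && s_kept < target && b[ord[K]] > 0.0) {
    s_kept += w0 * b[ord[K]];
    ++K;
  }
  if (max_n >= 2 && (double)K > guard_states)
    stop("grid oracle: %d kept states exceeds the enumeration guard (%g); "
         "coarsen the grid, reduce orientations, or raise tail_drop", (int)K, guard_states);
  double s_drop = s_total - s_kept;

  // lab-frame site coordinates of kept states
  std::vector<WaterC> kept(K);
  std::vector<double> hk(K); // w * b
  for (size_t a = 0; a < K; ++a) {
    size_t id = ord[a];
    int i = (int)(id / O), o = (int)(id % O);
    kept[a].o[0] = points(i, 0); kept[a].o[1] = points(i, 1); kept[a].o[2] = points(i, 2);
    for (int j = 0; j < 4; ++j) kept[a].quat[j] = quats(o, j);
    place_sites(mod, kept[a]);
    hk[a] = w0 * b[id];
  }

  int n_exact = std::min(max_n, 3);
  double zeta2_kept = 0.0, zeta3_kept = 0.0;

  // branch-and-bound pruning: states are sorted by weight, and the pair
  // Boltzmann boost is bounded by the strongest possible water-water
  // attraction (~8 kcal/mol for rigid 4-site water), so once the maximal
  // remaining contribution falls below a relative floor the inner loops
  // can stop early without bias beyond the floor
  const double boost = std::exp(p.beta * 8.0);
  const double rel_floor = 1e-10;

  // exact triples are limited to the heaviest Kt states (their own, deeper
  // truncation level; the triple term carries little weight at the B values
  // of interest and is refinement-checked like everything else)
  size_t Kt = (n_exact >= 3) ? std::min(K, (size_t)2000) : 0;

  if (n_exact >= 2) {
    std::vector<double> gmat;
    if (Kt > 0) gmat.assign(Kt * Kt, 0.0);
    for (size_t a = 0; a < K; ++a) {
      if (hk[a] * hk[a] * boost * (double)(K - a) <
          rel_floor * (zeta2_kept + 1e-300)) break;
      for (size_t c = a + 1; c < K; ++c) {
        if (hk[a] * hk[c] * boost < rel_floor * (zeta2_kept + 1e-300) &&
            c >= Kt) break;
        double u = water_water_energy(kept[a], kept[c], mod, p);
        double gg = (u == WATNET_INF) ? 0.0 : std::exp(-p.beta * u);
        zeta2_kept += hk[a] * hk[c] * gg;
        if (a < Kt && c < Kt) { gmat[a * Kt + c] = gg; gmat[c * Kt + a] = gg; }
      }
    }
    if (Kt > 0) {
      for (size_t a = 0; a < Kt; ++a) {
        for (size_t c = a + 1; c < Kt; ++c) {
          if (hk[a] * hk[c] * boost * boost * (double)Kt <
              rel_floor * (zeta3_kept + 1e-300)) break;
          double hac = hk[a] * hk[c] * gmat[a * Kt + c];
          if (hac == 0.0) continue;
          const double *ga = &gmat[a * Kt], *gc = &gmat[c * Kt];
          for (size_t d = c + 1; d < Kt; ++d)
            zeta3_kept += hac * hk[d] * ga[d] * gc[d];
        }
      }
    }
  }

  // completion: dropped states treated as non-interacting ideal background
  int NN = max_n;
  std::vector<double> zeta(NN + 1, 0.0);
  zeta[0] = 1.0;
  if (NN >= 1) zeta[1] = s_kept + s_drop;
  if (NN >= 2) zeta[2] = zeta2_kept + s_kept * s_drop + 0.5 * s_drop * s_drop;
  if (NN >= 3) zeta[3] = zeta3_kept + zeta2_kept * s_drop +
      0.5 * s_kept * s_drop * s_drop + s_drop * s_drop * s_drop / 6.0;
  for (int N = 4; N <= NN; ++N)
    zeta[N] = zeta[N - 1] * zeta[1] / (double)N; // ideal completion beyond order 3

  int nB = B.size();
  NumericVector lnXi(nB), meanN(nB);
  NumericMatrix PN(NN + 1, nB);
  for (int ib = 0; ib < nB; ++ib) {
    // log-sum-exp over terms t_N = B*N + log zeta_N
    double tmax = 0.0; // N = 0 term is 0
    std::vector<double> t(NN + 1);
    t[0] = 0.0;
    for (int N = 1; N <= NN; ++N) {
      t[N] = (zeta[N] > 0.0) ? B[ib] * N + std::log(zeta[N]) : -WATNET_INF;
      if (t[N] > tmax) tmax = t[N];
    }
    double s = 0.0, sN = 0.0;
    for (int N = 0; N <= NN; ++N) {
      double e = std::exp(t[N] - tmax);
      s += e; sN += N * e;
    }
    lnXi[ib] = tmax + std::log(s);
    meanN[ib] = sN / s;
    for (int N = 0; N <= NN; ++N) PN(N, ib) = std::exp(t[N] - tmax) / s;
  }

  return List::create(
    _["B"] = B, _["ln_xi"] = lnXi, _["mean_n"] = meanN, _["p_n"] = PN,
    _["zeta"] = NumericVector(zeta.begin(), zeta.end()),
    _["n_states"] = (double)P * O, _["n_kept"] = (double)K,
    _["weight_dropped"] = s_drop, _["n_exact"] = n_exact);
}
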