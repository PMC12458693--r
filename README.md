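# watnet

Binding-site water networks by grand canonical Monte Carlo, for
computational chemists and structural bioinformaticians who need to know
what a pocket's ordered waters cost — and what displacing them costs a
ligand series.

Protein subpockets often hold a small, cooperative network of ordered
waters. When a compound series grows substituents into the pocket, each new
group displaces a water and perturbs the stability of the rest; whether that
helps or hurts affinity is invisible to methods that treat waters
implicitly. `watnet` implements the workflow that makes this quantitative:

- **GCMC sampling.** Rigid waters are inserted/deleted/moved in a defined
  region in the μVT ensemble across a ladder of Adams B values (chemical
  potential), with replica exchange between adjacent B values. The Adams
  convention is folded so the ideal-gas law ⟨N⟩ = e^B is exact.
- **Grand canonical integration (GCI).** From d(βΩ)/dB = −⟨N⟩, the network
  binding free energy relative to bulk solvent reduces, at
  B_equil = βμ′_hyd + ln(V_GCMC/V°), to
  ΔG_bind = −kT ∫ ⟨N⟩ dB — the area under the titration curve
  (the bulk-reference and standard-state terms cancel exactly; see the
  methods vignette for the bookkeeping).
- **Hydration sites.** Sampled oxygen positions are clustered
  (average linkage, 2.4 Å cutoff), filtered at 30 % occupancy, and scored
  against crystallographic waters by the true positive rate
  TPR = TP/(TP+FN) with a 1.5 Å match threshold.
- **Alchemical legs.** Dual-topology transformations with softcore LJ and
  Coulomb potentials (δ, δ_c), a dummy bond between the two ligand copies'
  centres of geometry with coupled rigid-body moves, 16 λ windows with
  replica exchange, and an MBAR estimator (with an independent BAR
  cross-check).
- **Cycles.** Wet/dry alchemical legs plus the two network legs assemble
  into thermodynamic cycles with closure-error accounting:
  closure = |ΔG_wet + ΔG_net,A − ΔG_dry − ΔG_net,B|.

Everything is testable at desk scale through a synthetic cage-host
generator (tuned tripod-of-charges hydration sites, occluding/polar ligand
series) and an exact grid grand-partition oracle that enumerates
Ξ(B) = Σ_N e^{BN} ζ_N on a position × orientation grid with the same
normalisation as the sampler.

## Worked example

A two-site cage whose designed wells (−12 kcal/mol) hold a cooperative
two-water network; full B ladder, three repeats, then GCI and hydration-site
analysis:

```r
library(watnet)
params <- energy_params()                      # 298 K, 10 A cutoff, 0.5 A switch
spec   <- synthetic_system_spec(n_sites = 2, well_depths = -12, seed = 5)
host   <- make_cage_host(spec)                 # tripod-caged 2-water network
region <- simulation_region(gcmc_box_from_waters(host$crystal_water_oxygens, 1))
ref    <- bulk_water_reference()               # TIP4P bulk: mu_ex -6.2, V0 30

ladder <- run_gcmc_ladder(host, tip4p(), region, params, b_ladder(),
                          seed = 11, n_repeats = 3, record_frames = TRUE)
curve  <- occupancy_curve(ladder)
net    <- gci_binding_free_energy(curve, region, ref, params)
print(net)
#> <network_free_energy> dG = -1.987 +/- 0.028 kcal/mol (N_equil = 1.63 at B_equil = -10.61, trapezoid)

b_eq   <- equilibrium_b(ref, region, params)
i_eq   <- which.min(abs(b_ladder() - b_eq))
sites  <- filter_by_occupancy(cluster_water_sites(ladder$trajectories[[i_eq]]), 0.30)
print(true_positive_rate(sites, host$crystal_water_oxygens, 1.5))
#> <site_comparison> TPR = 1.000 (2 TP / 2 crystal sites, threshold 1.50 A)
print(round(as.data.frame(sites), 3))
#>        x      y      z occupancy n_members
#> 1 -2.247 -0.009 -0.274     0.808       854
#> 2  2.452  0.077  0.262     0.789       789
```

Reading the output: the two-water network is bound by −2.0 kcal/mol
relative to the same waters in bulk (mean ± SE over three repeats; the mean
occupancy at the equilibrium B value, 1.63, says the network is mostly but
not always full at physiological conditions). Clustering the production
frames at that B recovers both designed sites within 0.3 Å — every
crystallographic site has a predicted site within 1.5 Å, so the TPR is 1 —
with occupancies near 0.8, and `plot(curve)` draws the titration curve the
integral ran over. Alchemical legs
(`dual_topology_system()` → `run_alchemical_leg()` → `mbar_free_energy()`)
and `free_energy_cycle()` / `closure_error()` extend this to compound
transformations; `run_pipeline(run_config(...))` drives the whole chain
from one seeded configuration, and `report()` prints the bundle.

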