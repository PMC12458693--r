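---
title: "Water-network free energies by grand canonical Monte Carlo: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-network free energies by grand canonical Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watnet)
```

## The problem

Ordered water molecules inside a protein binding pocket often form a small,
cooperative hydrogen-bonded network. When a ligand series grows substituents
into such a pocket, each new group can displace one of those waters and
perturb the stability of the ones that remain — sometimes paying a large
hidden free-energy price, sometimes gaining new bridging interactions. The
quantities that make this tractable are (i) the binding free energy of the
water network itself, relative to bulk solvent, in the presence of each
compound, and (ii) the alchemical transformation free energy between
consecutive compounds with and without the network present. Arranged as a
thermodynamic cycle these numbers must sum to zero, so the closure error is a
built-in convergence diagnostic.

`watnet` implements that workflow end to end at desk scale: a grand canonical
Monte Carlo (GCMC) water sampler over an Adams B-value ladder, grand
canonical integration (GCI) of the titration curves, hydration-site
clustering scored against crystallographic waters, dual-topology alchemical
legs estimated with MBAR, and cycle assembly. A synthetic cage-host
generator plus an exact grid grand-partition oracle make every stage testable
without external data or cluster-scale computing.

## Model and sampling ensemble

**System.** A rigid host (fixed interaction sites with Lennard-Jones and
point-charge parameters) sits in an implicit droplet of radius $R$ (default
30 Å); water oxygens outside the droplet feel a half-harmonic restraint
$\tfrac{1}{2}k(d-R)^2$ with $k = 1.5$ kcal mol$^{-1}$ Å$^{-2}$. There are no
periodic boundaries. Waters are rigid TIP4P molecules (O–H 0.9572 Å, H–O–H
104.52°, M site 0.15 Å along the bisector, $q_H = +0.52\,e$,
$q_M = -1.04\,e$, $\sigma_O = 3.15365$ Å, $\epsilon_O = 0.155$ kcal/mol);
other rigid 3/4-site models plug in through `water_model()`.

**Energetics.** Pairwise LJ (Lorentz–Berthelot combination) plus Coulomb
($C = 332.0637$ kcal Å mol$^{-1}$ e$^{-2}$) with a 10 Å cutoff and a
CHARMM-style quintic energy-switching function over the last 0.5 Å,
$$S(r) = \frac{(r_c^2-r^2)^2\,(r_c^2+2r^2-3r_{on}^2)}{(r_c^2-r_{on}^2)^3},
\qquad r_{on} = r_c - w,$$
which is 1 below $r_{on}$, 0 at $r_c$, and $C^1$ at both joins. The cutoff is
applied per molecule pair on the oxygen–oxygen (water–water) or oxygen–site
(host–water) distance, so a molecule's sites switch off together and a
dipole is never split across the cutoff. Host–host terms are constant for a
rigid host and excluded everywhere.

**GCMC.** Waters inside an axis-aligned box (the bounding box of the
network's oxygens plus 1 Å padding) are sampled in the $\mu$VT ensemble.
The chemical potential enters through the Adams parameter $B$; the engine
folds the thermal-wavelength constant into $B$ so that insertion acceptance
is $\min\{1, e^{B}/(N{+}1)\,e^{-\beta\Delta U}\}$, deletion
$\min\{1, N e^{-B} e^{-\beta\Delta U}\}$, and the ideal-gas law
$\langle N\rangle = e^{B}$ is *exact*. Displacement moves (random
translation up to 0.25 Å per axis, rotation up to $\pi/4$) reject any
proposal that carries an oxygen across the box boundary, so insertion and
deletion are the only region-count-changing moves; the slight sampling
inefficiency buys unambiguous bookkeeping. Default move mix: 35 %
insertion, 35 % deletion, 20 % box-water displacement, 10 % bulk-water
displacement (the literature specifies move counts, not a mix, so this is a
package default, tunable in `move_schedule()`).

Runs use a two-phase equilibration (box-only sampling, then all waters)
followed by production with samples every `sample_interval` moves. Replica
exchange between adjacent B values swaps whole configurations with
probability $\min\{1, \exp[(B_m-B_n)(N_n-N_m)]\}$, alternating even/odd
pairs between sweeps. One master seed derives an independent
`xoshiro256++` stream per (repeat, replica), so ladders are bit-reproducible.

## Titration curves and grand canonical integration

At each B, the mean region count over production samples gives one point of
the titration curve; three independent repeats are pooled as mean ±
SD/$\sqrt{3}$ (`occupancy_curve()`). The default ladder is 24 values from
$-19$ to $-7.5$ in steps of 0.5.

From $d(\beta\Omega)/dB = -\langle N\rangle$, integrating the curve gives
the grand-potential change. The network binding free energy relative to
bulk follows by anchoring B to physical water: with
$B_{equil} = \beta\mu'_{hyd} + \ln(V_{GCMC}/V^\circ)$
(defaults $\mu'_{hyd} = -6.2$ kcal/mol, $V^\circ = 30$ Å$^3$, the standard
literature values for TIP4P at 298 K, both explicit configuration values),
the full bookkeeping is
$$\Delta G_{bind} = \Delta\Omega + \mu(B_{equil})\,N - N\,\mu_{bulk},$$
where $\beta\mu(B) = B - \ln(V_{GCMC}/\Lambda^3)$ and
$\beta\mu_{bulk} = \beta\mu'_{hyd} - \ln(V^\circ/\Lambda^3)$. Evaluated *at*
$B_{equil}$ the chemical-potential and standard-state terms cancel exactly
— including the unknown $\Lambda$ — leaving
$$\Delta G_{bind} = -kT\int_{B_{empty}}^{B_{equil}}\langle N\rangle\,dB,$$
the "area underneath the titration curve". `gci_binding_free_energy()`
integrates per repeat (trapezoid on the simulated grid by default; an
optional monotone logistic fit serves sparse ladders and the output records
which was used), requires the curve to be essentially empty at the lowest B
(pooled occupancy ≤ 0.05, else it errors advising a ladder extension), and
reports the pooled mean ± SE. $N_{equil}$ is the pooled occupancy at the
grid point nearest $B_{equil}$, rounded only for reporting, never inside
the integral. The grid oracle (below) shares the identical normalisation,
so sampled GCI and exact enumeration are directly comparable:
$-kT[\ln\Xi(B_{equil}) - \ln\Xi(B_{empty})]$.

## Hydration sites and crystal-water comparison

Water oxygen positions pooled over production frames at the B value nearest
$B_{equil}$ are clustered by average-linkage hierarchical clustering
(`stats::hclust`) cut at 2.4 Å linkage distance. A site's occupancy is the
fraction of frames contributing at least one member — capped at one even if
a cluster transiently holds two waters, so reported occupancies are true
frame fractions. Sites below 30 % occupancy are dropped (inclusive
threshold: exactly 30 % is kept). Against crystallographic waters the true
positive rate counts, per crystal site, whether any predicted centroid lies
within 1.5 Å (inclusive); one predicted site may satisfy several crystal
sites, the literal reading of the sensitivity definition, which we note for
comparability with greedy one-to-one matchers.

## Alchemical legs and MBAR

Dual topology: both end-state ligands are present as rigid bodies;
environment–B interactions are weighted by $\lambda$ and environment–A by
$1-\lambda$ through softcore forms
$$U_{LJ}^{sc} = 4\epsilon\,w\left[\frac{1}{(\delta(1-w)+x)^2} -
\frac{1}{\delta(1-w)+x}\right],\; x = (r/\sigma)^6; \qquad
U_{C}^{sc} = \frac{C q_a q_b\, w}{\sqrt{\delta_c(1-w)+r^2}},$$
with $\delta = 0.2$ and $\delta_c$ per transformation (2.0–2.5). These are
the common one-parameter, $\lambda$-power-1 convention: finite at $r = 0$
for $w < 1$, reducing exactly to the plain potentials at $w = 1$ and to
zero at $w = 0$. (Because the softcore denominators depend on $w$, two
superposed identical ligands at weights $w$ and $1-w$ do *not* sum exactly
to the single-ligand energy at intermediate $\lambda$; the identity holds
exactly at the endpoints, which is what the estimator uses.) A–B cross
interactions are excluded, a zero-rest-length harmonic "dummy bond"
(default $k = 10$ kcal mol$^{-1}$ Å$^{-2}$) ties the two centres of
geometry, and rigid-body moves propose identical translations and rotations
to both copies, so the bond length is conserved by construction. A
flat-bottom centre-of-geometry restraint (default $k = 25$, radius 1 Å)
keeps a weakly coupled pair from drifting out of the site — a standard
positional restraint; it is $\lambda$-independent and cancels in the
free-energy difference.

Sampling is canonical (fixed N) per window over a ladder of 16 equally
spaced $\lambda$ values with replica exchange between adjacent windows; at
every sample the reduced potential is evaluated at all windows. MBAR solves
the self-consistent reweighting equations (ten stabilising self-consistent
sweeps, then Newton–Raphson on the $K-1$ free differences of the convex
extended-bridge-sampling objective) to $10^{-10}$ on the reduced free
energies. Reduced potentials contain only the $\lambda$-dependent terms;
$\lambda$-independent, configuration-dependent energy is a common offset
per sample and cancels identically in the MBAR equations. Uncertainty is
estimated by bootstrap over samples within windows plus, when repeats are
run, the across-repeat SD; we chose the bootstrap as the asymptotic
covariance estimate because it needs no analytic formula and behaves
sensibly under the correlated samples a Markov chain produces (with the
caveat that strong autocorrelation still biases it low — the repeat SD is
the more conservative number). An adjacent-window overlap diagnostic flags
divergent uncertainties; a two-state Bennett-acceptance-ratio solver is
included as an independent cross-check and agrees with two-window MBAR to
numerical precision.

**Cycle consistency with a rigid host.** In this artifact the host (and any
bound compound) is rigid during GCMC, so the network legs of a cycle see
the ligand frozen at its crystallographic pose. For the alchemical legs of
a *cycle* we therefore freeze the ligand pose too
(`alch_schedule(sample_ligand = FALSE)`): otherwise the alchemical legs
would integrate over ligand poses the network legs never see, and the
cycle would carry a spurious non-closure. Pose sampling remains on by
default for standalone transformations and is exercised by the
antisymmetry tests. The displaced water of a substitution is handled by
defining both network legs over the retained (common) water set, whose
size the cycle builder takes explicitly.

## The synthetic systems and what they do (and do not) show

`make_cage_host()` builds a rigid polar cavity with 1–7 designed hydration
sites (default: a linear chain, 4.5 Å spacing). Each site is caged by a
tripod of three positive partial charges at 2.7 Å (25° off the site axis,
axes alternating ±z along the chain, a small seed-derived azimuthal twist)
plus soft LJ bodies, and a $-3q$ compensator on the axis so each cage unit
is net neutral — without the compensator the monopole field of one tripod
reaches neighbouring sites and the well depths stop being independently
tunable. Tripod charges are tuned by bisection, with all other units
present, until the *relaxed* well depth at each site (orientation scan over
a deterministic super-Fibonacci rotation set, then Nelder–Mead confined to
the local basin) hits the requested value within 0.2 kcal/mol; the build
verifies that each minimum sits within 0.5 Å of its designed position and
errors otherwise. Designed positions double as the synthetic "crystal"
waters. Default well depth is $-12$ kcal/mol: deep enough that sites are
occupied at $B_{equil}$ against bulk water at $\mu'_{hyd} = -6.2$ kcal/mol,
as real conserved network waters are.

Ligand series: compound $k$ places an occluding body (σ = 3.2 Å LJ sphere,
charge $-0.12\,e$) at each site it blocks — a mildly unfavourable
replacement for a hydrogen-bonding neighbour, since the remaining caged
waters expose their oxygen face outward — and optional polar contacts
(positive, hydrogen-bond-donor-like charges at 2.9 Å from a named surviving
site, placed toward the nearest blocked site) that stabilise the remaining
network, emulating scaffold atoms that pick up new water interactions.
These constructions reproduce, by design, the qualitative arc of a
water-displacement series: blocking a site destabilises the remaining
network, adding polar contacts restores stability, blocking further sites
destabilises again — and the tests assert those *signs* against the exact
oracle, never magnitudes against published numbers.

What the synthetic systems deliberately lack: host flexibility, explicit
bulk solvent around the droplet, chemically realistic ligands, long-range
electrostatics beyond the 10 Å switch, and ions. Passing tests therefore
demonstrate the correctness of the sampling, integration, clustering and
estimation machinery — not force-field accuracy on real complexes, which
additionally needs cluster-scale sampling of flexible, fully parametrised
systems.

## The exact oracle

`grid_oracle()` enumerates the grand partition function on a position grid
times a deterministic low-discrepancy orientation set (super-Fibonacci
spirals on SO(3)): $\Xi(B) = \sum_N e^{BN}\zeta_N$ with $\zeta_N$ the
$N$-water configurational sum over grid states, sharing the engine's Adams
normalisation so ideal-gas $\langle N\rangle = e^B$ emerges exactly in the
fine-grid limit. Water–water terms are enumerated exactly up to $N = 3$
over the states covering $1 - $ `tail_drop` of the one-body weight (sorted
by Boltzmann weight, with branch-and-bound pruning bounded by the maximal
~8 kcal/mol water-pair attraction); dropped low-weight states and $N > 3$
enter through a non-interacting completion. Every approximation is a knob
(`spatial_step`, default 0.25 Å; `n_orientations`, default 256;
`tail_drop`, default $10^{-3}$) checked by refinement in the tests, and
enumeration guards error out rather than silently truncating. The oracle's
self-consistency ($-kT\,\Delta\ln\Xi$ equals the trapezoid of its own
$\langle N\rangle$) and its ideal-gas and deep-well limits are tested
independently of the sampler.

## Numerical choices and degenerate inputs

- Box membership uses the oxygen position only, closed on all sides.
- Zero-volume GCMC boxes, empty position lists, occupancy curves that never
  empty or never reach $B_{equil}$, empty crystal-water lists for TPR, and
  sidecar/atom count mismatches all raise immediate, specific errors.
- A flat-zero titration curve yields $\Delta G = 0$ with `n_equil = 0` and
  an `empty` flag rather than an error.
- Hard overlaps ($r \to 0$) give $+\infty$ energy and auto-rejection in
  samplers, but an explicit error in the scalar `pair_energy()` contract.
- Incremental move energetics are validated against full recomputation
  (drift ≤ $10^{-6}$ kcal/mol over $10^4$-move stretches) and against an
  independent pure-R double-loop implementation.
- Linkage ties in `hclust` are resolved by R's deterministic merge order;
  clustering is invariant to frame order and rigid motions (tested).

## Desk-scale study conditions

The tests and the acceptance script run, per B value, 10k + 5k
equilibration and 50k production moves (samples every 50) over the full
24-value ladder with 3 repeats — about 3.6 M moves per system — and
alchemical legs of 12–16 windows with 40–80k production moves each. These
sizes were chosen so every oracle comparison resolves its tolerance with
seed-stable margins on a single CPU; `paper_schedule()` carries the
full-scale settings (5 M + 5 M + 40 M moves, sampling and replica exchange
every 100k) appropriate for cluster runs on real, flexible complexes.

## Known limitations

- Rigid hosts and ligands: no conformational reorganisation energy.
- Energy-switched cutoff electrostatics; no Ewald/reaction field.
- Bootstrap uncertainties understate strongly autocorrelated samplers; use
  repeats for honest errors (the default everywhere repeats matter).
- The oracle is exact only in the refinement limit; its defaults resolve
  the toy systems to ~0.05 kcal/mol, well inside the 0.3 kcal/mol bands it
  arbitrates, but custom systems should rerun the refinement checks.
- Ions are not sampled; chloride seen in real pocket structures would need
  an extension of the species list.
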