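---
title: "Methods: multilevel stochastic simulation of Notch–Delta patterning in growing tissue"
author: "tissuessa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel stochastic simulation of Notch-Delta patterning in growing tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `tissuessa`, the
numerical choices behind them, and what the test suite does and does not
establish. It is a methods document: every quantitative statement here is
recomputed by the tests or by `scripts/acceptance.R`, not asserted from
memory.

## 1. The signaling model

Lateral inhibition between the transmembrane proteins Notch and Delta is
the canonical mechanism for fine-grained fate patterns in epithelia: a
cell that commits to a fate raises Delta, which activates Notch in its
contacts and suppresses the same fate there. The classical two-species
form (`collier_rhs`) is

    n' = f(<d>) - n,    d' = const * (g(n) - d),

with `f` increasing, `g` decreasing, and `<d>` the mean Delta over the
junctional neighbors. `f` and `g` are caller-supplied; the package
defaults are Hill forms `f(x) = x^2/(0.01 + x^2)`,
`g(x) = 1/(1 + 100 x^2)` and `const = 1`, a standard parameterization in
which junctional coupling on a hexagonal sheet produces an alternating
high/low-Delta pattern. This two-species model is kept as a reference
point; the working model adds a Notch reporter and protrusional
signaling.

The three-species model (`ndr_rhs`) is non-dimensional, per cell *i*:

    n' = beta_n - d_in n / k_t - d n / k_c - n
    d' = beta_d / (1 + r^m) - d n_in / k_t - d n / k_c - d
    r' = beta_r (d_out n)^s / (k_rs + (d_out n)^s) - r

Delta is repressed by the reporter `r`, which is activated jointly by the
cell's own Notch and the *outgoing* Delta bound from its contacts. The
signal sums distinguish junctional sets `J(i)` (superscript *a*) from
protrusional sets `P(i)` (superscript *b*) and weight them separately:

    d_in  = w_a sum_{J(i)} d_j + w_b sum_{P(i)} d_j
    d_out = q_a sum_{J(i)} d_j + q_b sum_{P(i)} d_j
    n_in  = w_a sum_{J(i)} n_j + w_b sum_{P(i)} n_j

All defaults (`pathway_params()`) are the baseline used throughout:
`beta = [100, 500, 3e5]`, `k = [2, 0.5, 1e7]`, `m = s = 2`, `Omega = 400`,
weights `[1, 1, 1, 1]`. Differential weightings
(`[1, 0.001, 0.06, 0.06]`, and `[1, 0.001, 0.2, 0.15]` with polarized
protrusions) are shipped as the `"spots"` and `"polarized"` presets; they
shift the pattern from alternating cells toward sparse spots and
stripe-like arrangements.

### Stochastic interpretation

`ndr_propensities` converts the ODE terms into nine reaction channels at
system volume `Omega` (counts `N = Omega n`, etc.), in a fixed, documented
order: productions `beta_n Omega`, `beta_d Omega r1`, `beta_r Omega r2`
with `r1 = 1/(1 + (R/Omega)^m)` and
`r2 = u^s/(k_rs + u^s)`, `u = d_out N / Omega^2`; signal-mediated
degradations `N d_in/(k_t Omega)` and `D n_in/(k_t Omega)`; cis
annihilation `N D/(k_c Omega)`; and unit-rate decays of N, D, R. The
channel order is part of the package contract because trajectories are
reproducible only if the order never changes.

### Signal freezing and the adaptive chunk

Exact joint simulation of all cells would force every Delta event to
invalidate the neighbors' propensities. Instead the cross-cell signals are
frozen over chunks `[t, t + dtau)` and every cell is advanced
independently and exactly within the chunk (`ssa_population`). The chunk
is conservative: a forward-Euler step of the deterministic model may move
the state by about 5%,

    dtau = chunk_safety * ||x|| / ||f(x)||,   chunk_safety = 0.05,

with `x` the concatenated concentration vector of the whole population.
Choices made here, where more than one reading is defensible:

* **Norm**: Euclidean, over the full concatenated vector — the
  conventional reading of an unqualified norm, and scale-free for linear
  drift (tested as an invariance).
* **Bounds**: `dtau` is clipped to `[1e-6, 0.5]`. The ratio rule is
  unbounded at equilibrium (`||f|| -> 0`) and collapses at a zero state;
  the cap keeps signal refreshes happening at a minimal cadence, the
  floor guards degenerate starts. Both are configurable.
* **Split-step error**: freezing signals is an operator-splitting
  approximation with strong error of order `dtau^(1/2)`. The acceptance
  suite checks weak consistency on a two-cell system at `Omega = 4000`:
  halving `chunk_safety` moves the ensemble mean Delta at `t = 5` by less
  than the Monte-Carlo standard error of 200 replicates.
* **Initial condition** for pattern runs: the model needs heterogeneity to
  break symmetry. `random_initial_counts` draws, per cell and species,
  `Poisson(Omega * u)` counts with `u ~ Uniform(0, 1)` for N and D and
  starts R at 0 — broad enough to span the basins of the patterned
  states without favoring any phase.

## 2. The spatial single-cell layer (RDME)

Within one cell, space is discretized into voxels small enough to be well
stirred; reactions run in every voxel and diffusion becomes a first-order
jump between mesh neighbors at per-molecule rate

    q_ij = gamma (e_ij / d_ij) / V_i,

the finite-volume-consistent discretization of the Laplacian on the dual
mesh (`diffusion_jump_rates`); `gamma = 1/Omega` for all three species by
default. Volume scalings per voxel follow the standard mesoscopic rules:
productions scale with `V_i` (so the whole cell produces at `beta Omega`),
linear decays are volume-free, and the bimolecular cis term uses
`1/(k_c V_i)`. Two deliberate choices:

* **Signals stay whole-cell quantities.** The signal-mediated degradation
  of N runs at `d_in/(k_t Omega)` in every voxel, with `d_in` computed
  from neighbor-cell totals, because the pathway defines signaling
  between cells, not between voxels; membrane-localized reception is out
  of scope (see Limitations).
* **The mesh fixture is a deterministic polar mesh.** `cell_mesh_fixture`
  builds a disc as a central voxel plus concentric rings of annular
  sectors (ring k holds 6k voxels; four layers give 37 voxels for the
  default target of 40), with `e/d` ratios from the actual sector
  geometry and volumes scaled to sum exactly to `Omega`. A concentric
  inner region marks the nucleus, geometrically only. A deterministic
  construction keeps every test and trajectory reproducible; the voxel
  count tolerance accepted by the tests is [30, 50].

`nsm` samples the exact reaction–diffusion process with the Next
Subvolume Method: per-voxel next-event times in an indexed binary heap
(ties broken by voxel index, for determinism), per event a choice of
diffusion versus reaction proportional to the voxel's summed propensities,
and a next-reaction-style rescaling of the affected neighbor's clock. A
single-voxel mesh reduces the sampler to the well-stirred model; the
acceptance suite checks that reduction distributionally against the
direct-method driver, and checks the sampler against an independent plain-R
direct-method implementation on a three-voxel toy.

## 3. The population layer (DLCM)

Cells occupy lattice voxels (hexagonal by default, square supported), at
most two per voxel. Voxels at the carrying capacity source a cellular
pressure

    -L p = s(u)  on the populated set,   p = 0 on the free boundary,

with `s = 1` where `u = 2` and `L` the lattice Laplacian (`e/d = 1` on
these uniform lattices). Movement candidates are ordered voxel pairs with
`u_i > u_j`; the rate is `D * max(0, p_i - p_j)`. Downhill-only conversion
is forced by non-negativity of rates; movements between equally occupied
voxels are disabled. With no over-occupied voxel the pressure — and hence
every movement rate — vanishes, making `u <= 1` configurations absorbing.

The conversion factor `D` may depend on position and movement type, and
the package uses that freedom once more: `D = 0` for vacating moves that
would fragment the populated set (a lone rim cell stepping off the
tissue while a distant division resolves). Without this rule the strictly
pressure-proportional rates let single cells detach transiently, because
the discrete Green's function is positive everywhere in the connected
component; with it, the population stays edge-connected after every
event, which is also what the replay-based checks assert. Setting
`growth_params(keep_connected = FALSE)` restores the pure conversion
(useful for comparing against the hand-solved one-dimensional examples,
where end-of-chain moves are otherwise legal candidates at rate `p_i`).

**Nutrient model.** Growth is fed from the boundary: the quasi-static
field solves `-L c = -kappa u` with `c = c_b` on the free boundary
(clamped below at zero), and a cell divides at rate `mu` only if it is
alone in its voxel and `c >= c_thr`. This is the minimal linear
consumption–diffusion closure that realizes boundary-fed, consumed,
diffusing nutrition; the defaults `kappa = 0.02`, `c_b = 1`,
`c_thr = 0.5`, `mu = 1` were chosen once so that a population of order a
thousand cells develops a nutrient-starved core (the interior
concentration falls below threshold at a radius of roughly ten voxels)
while rim cells keep dividing — the regime in which division visibly
concentrates near the boundary. The acceptance suite verifies this bias
as a property (mean distance-to-boundary of dividing cells below the
population mean), not as a fitted curve.

`simulate_population` is Gillespie's direct method over all movement and
division rates, re-solving both sparse linear systems after every event.
That is the correctness-first choice; factorization reuse across events
would be the natural optimization but is not needed at the problem sizes
used here. Every event is appended to a replayable log; a `divide` row
records the daughter's id so replays are exact.

## 4. Coupling the layers

The paper-scale experiments use one-way coupling: record a growth
trajectory once, then simulate the molecular layer over it
(`run_coupled`). Per iteration the driver aggregates per-cell totals into
signals, picks `dtau` as above, advances every cell's mesh independently
to the next chunk boundary, output time, or population event — whichever
comes first — and applies due events. Conventions:

* Ties between an event time and a chunk boundary are processed
  event-first.
* A move carries the cell's entire per-voxel state unchanged; the contact
  graph is rebuilt from the new positions after every event (tested
  against a fresh full rebuild).
* A division splits every molecule of every species independently with
  probability 1/2 between the daughters (`divide_counts`), exact
  conservation per species, each share redistributed over the daughter
  mesh proportionally to voxel volume; both daughters start in the parent
  voxel at occupancy 2 and are separated by the pressure dynamics.
  Sharing all three species (not only N and D) is the default for mass
  conservation; `species = "nd"` reproduces the variant where the
  reporter is not inherited.
* Cells sharing a voxel are junctional contacts of each other, as are
  cells in edge-adjacent voxels; protrusional contacts use the same
  distance/sector rule as the static lattice, on voxel centers.
* Two-way coupling (population rates reading molecular state) fits the
  same loop, but no shipped experiment uses it; the recorded-log mode is
  the supported path.

## 5. Contact geometry

Junctional contacts are the up-to-six hexagonal neighbors at center
distance 2 (cell radii are the length unit). Protrusional contacts
(`protrusional_contacts`) are cells at center distance in `(2, l]` lying
inside a protrusion sector of the source — and, by the **mutual-reach
rule**, reciprocally inside a sector of the target. The symmetric rule is
the one the running model's weight sets assume; a directed variant
(protrusion-to-membrane vs membrane-to-protrusion) is representable in
principle but deliberately not implemented, since no shipped experiment
specifies distinct reach rules. Sector edges are closed with a `1e-9`
angular tolerance; `width = 2*pi` short-circuits to isotropic. With
`l = 3.5` an interior cell's protrusional set is exactly the six
second-ring cells at distance `2 sqrt(3) ~ 3.46` (the ring at distance 4
is excluded); polarized presets read "horizontal protrusions" as the two
directions `{0, pi}` shared by all cells.

## 6. Problem sizes, seeds and performance

The direct-method and NSM inner loops are compiled (Rcpp): the reporter
species alone runs at propensities of order `10^6` per patterned cell, so
a 100-cell lattice to `t = 200` executes on the order of `10^10` exact
events — minutes in compiled code. Sizes used by the shipped checks, all
on one CPU:

* pattern formation: 10 × 10 hexagonal lattice to `t = 200` (the long
  pole, roughly ten minutes);
* stationary birth–death: 12 000 samples spaced 3 time units;
* thermodynamic limit: volumes `{4e2, 4e3, 4e4}` with `{400, 200, 100}`
  replicates over a short transient;
* growth: 300 cells in the test suite, 1000 in the acceptance script;
* split-step consistency: 2 cells at `Omega = 4000`, 200 replicates.

All randomness flows through either R's RNG (population layer, seeds,
initial conditions) or a xoshiro256++ stream seeded per compiled call from
R's RNG, so a single `set.seed()`/`seed =` argument pins an entire run.

## 7. What the synthetic experiments do and do not show

Everything here is simulation from configuration; there is no external
data. The generator's defaults emulate the study conditions: a static
hexagonal epithelium for the patterning runs, a boundary-fed growing
colony for the population runs, and their combination for the coupled
runs. Real epithelia differ in ways the model deliberately omits: cells
are not congruent hexagons, protrusions grow and retract dynamically
rather than defining a static contact set, reception is
membrane-localized (here signals act uniformly over the cell volume),
nuclei and membranes carry distinct reaction sets, and tissues grow with
adhesion, death, and sub-capacity crowding effects. Passing tests
therefore certify the *method* — exactness of the samplers, correctness
of the discrete operators, conservation and reproducibility contracts,
and the qualitative pattern classes — not quantitative agreement with any
particular tissue.

## 8. Known limitations

* Unstructured population grids (variable voxel volumes at the tissue
  level) are not supported; lattices are uniform with `e/d = 1`.
* No apoptosis, adhesion, or density effects below the carrying capacity.
* The nutrient closure is a design choice; any monotone boundary-fed
  consumption model would serve, and none is calibrated to data.
* The split-step scheme's chunk cap (`dtau_max = 0.5`) bounds how stale
  signals can get at equilibrium; applications with much faster signaling
  than the defaults should lower it.
* Three-dimensional geometries are out of scope.
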