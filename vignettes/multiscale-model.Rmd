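---
title: "The multiscale vascular tumour growth model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multiscale vascular tumour growth model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorvasc)
```

# Overview

`tumorvasc` simulates vascular tumour growth in three dimensions by coupling
five layers on one regular lattice:

1. **Blood flow** through a graph of vessel segments (Poiseuille flow,
   Kirchhoff conservation, prescribed inlet/outlet pressures, haematocrit
   transport).
2. **Vascular remodelling**: structural adaptation of segment radii and
   pruning of chronically under-perfused segments.
3. **Angiogenesis**: VEGF-dependent sprouting with spatial exclusion,
   chemotactic tip-cell random walks, and anastomosis.
4. **Diffusible fields**: quasi-steady reaction–diffusion of oxygen and
   VEGF with vessel and cell source/sink terms.
5. **Cells**: individual normal and cancer cells with oxygen-dependent
   cell-cycle progression, p53 and intracellular VEGF kinetics, quiescence,
   death rules, movement and division.

Every macro time-step of `dt = 30` min performs, in fixed order: field
solves (oxygen, then VEGF), cell updates (subcellular state, death,
movement, division, in stable id order), tip-cell steps with anastomosis
checks, then the vessel update (flow, haematocrit, one radius-adaptation
pass, pruning) and finally sprout initiation. This ordering is part of the
determinism contract: with a fixed seed the whole trajectory is bitwise
reproducible. All stochastic draws come from R's default Mersenne–Twister
stream in a documented order (cells by id, then tips in creation order,
then candidate sprout sites in lexicographic order).

# The lattice

The domain is a regular grid of voxel-centred sites (default spacing
`40 µm`; a site holds at most `capacity = 1` normal or cancer cell by
default, so tissue is loosely packed; endothelial tips and vessels do not
count against the capacity). Each axis independently carries either a
*reflecting* or a *periodic* boundary condition. Reflecting boundaries are
realised by exclusion: a move off the lattice is simply not offered, and
the field discretisation drops the missing flux (zero-flux closure).
Periodic axes wrap indices modulo the axis extent, and *all* geometric
predicates (neighbourhoods, the sprout exclusion radius, anastomosis,
segment lengths) use minimal-image displacements, so structures interact
coherently across the seam.

# Blood flow and haematocrit

Vessel segments connect face-adjacent lattice nodes. Each segment has
radius $R$, length $L$ (one lattice spacing), and an apparent viscosity
$\mu(R, H)$ given by plasma viscosity (1.2 cP) times the published in-vivo
relative viscosity law of the structural-adaptation literature (diameter-
and haematocrit-dependent, with the Fåhræus–Lindqvist minimum and the
endothelial wall-layer factor). Conductance is Poiseuille,
$G = \pi R^4 / (8 \mu L)$. Prescribing pressures at inlets and outlets and
imposing volumetric conservation at interior nodes yields a sparse linear
system solved by **direct sparse LU factorisation** (`Matrix`): perfusion
decisions hinge on whether tiny flows are genuinely zero, so the flow
solve is held to direct-solver accuracy (interior-node imbalance
$\le 10^{-10}$ relative, enforced in tests). Segments with
$|Q| < q_{floor}$ are flagged unperfused.

Haematocrit enters at inlets ($H_{in} = 0.45$) and propagates by red-cell
flux conservation. Because steady Kirchhoff flow is acyclic (flow always
runs down pressure), nodes are processed in order of decreasing solved
pressure; at diverging bifurcations the red-cell flux splits in proportion
to the volumetric flows (all outflows carry the node's mixed haematocrit).
A boundary node that emits more volume than it receives supplies plasma —
dilution, never red-cell creation. A phase-separation (plasma-skimming)
variant can be layered on this contract but is not the default.

Wall shear stress is $\tau = 4\mu|Q| / (\pi R^3)$, equivalently
$|\Delta P| R / (2L)$; both forms agree to machine precision on solved
states and the equivalence is pinned by a test.

# Vascular adaptation and pruning

Radii evolve **once per macro step** — they are *not* iterated to a steady
state within a step, reflecting the assumption that vascular adaptation
operates on the same timescale as cell movement and proliferation:

$$R \leftarrow \mathrm{clamp}\!\left(R\,(1 + \Delta t\, S_{tot}),\; R_{min},\, R_{max}\right),$$

with (each term independently switchable, so the reduced wall-shear +
shrinkage model can be studied in isolation)

$$S_{tot} = k_w \log_{10}\!\big(1 + \tau/\tau_{ref}\big)
          - k_p \log_{10}\!\big(1 + P/P_{ref}\big)
          + k_m \log_{10}\!\left(1 + \frac{Q_{ref}}{(|Q|H + 1)(1 + O_2)}\right)
          - k_s .$$

The stimulus families (wall-shear growth, pressure set-point, metabolic
demand, shrinking tendency) follow the structural-adaptation lineage; the
numeric constants (`k_w = k_p = k_m = 5e-4` per min, `k_s = 6e-4` per min,
$\tau_{ref} = 1$ dyn cm⁻², $P_{ref} = 20$ mmHg, $Q_{ref} = 2\times10^5$
µm³ min⁻¹) are desk-scale defaults chosen so that one 30-min step changes a
radius by at most a few percent. With fixed boundary pressures the
wall-shear feedback is positive (a growing vessel raises its own shear),
so well-perfused vessels drift toward $R_{max} = 25$ µm and starved ones
toward $R_{min} = 2$ µm; the clamp bounds this known instability and the
metabolic term protects low-flux vessels that still carry red cells.

Segments whose shear stays below $\tau_{crit} = 3$ dyn cm⁻² (or that are
unperfused) accumulate a low-flow clock; the clock resets on recovery and
the segment is removed when the clock *reaches* `t_prune = 600` min — so a
segment with zero flow from birth disappears after exactly
$\lceil t_{prune}/\Delta t \rceil$ steps. Unreferenced interior nodes are
dropped with their segments.

# Angiogenesis

Sprouting is VEGF-limited and saturating: a vessel-occupied site initiates
a sprout in a step with probability
$p = \Delta t\, P_{max}\, V/(V + V_{1/2})$ (capped at 1), provided no
active sprout origin lies within the exclusion radius
$R_{ex} = 60\ \mu m$ (minimal-image distance). The exclusion radius is the
lever that controls how densely parent vessels can sprout; the saturating
form honours the constraint that sprouting increases with VEGF.

Tips perform one biased step per macro step: admissible lattice neighbours
are weighted by $\max(\epsilon,\, 1 + \chi\,(V_{nb} - V_{tip}))$ with
$\chi = 2$ per VEGF unit and a floor $\epsilon = 0.01$ that keeps the walk
irreducible against adverse gradients. Tips traverse cell-occupied sites
freely. When a tip reaches a vessel site other than its own origin, or the
current site of another tip, the whole path is spliced into the network as
unit segments of radius $R_{init} = 6\ \mu m$ — duplicate segments are
never created, and the new vessels join the flow system at the next vessel
update (unconnected sprouts live entirely outside the flow solve, which
keeps the Kirchhoff system nonsingular). A sprout that has not connected
within `t_sprout_death = 3000` min dies back without trace. The enhanced
chemotaxis scenario multiplies $\chi$ by 10, which measurably increases
tip drift along a fixed gradient (asserted as an ensemble test).

# Oxygen and VEGF fields

Both fields satisfy quasi-steady elliptic reaction–diffusion equations,

$$0 = D \nabla^2 c - (\lambda + s(x))\,c + q(x),$$

discretised with the 7-point stencil (zero-flux closure on reflecting
axes, wrap coupling on periodic axes) and re-solved once per macro step —
diffusion equilibrates far faster than cells move. Oxygen: $D = 2.5\times
10^4$ µm² min⁻¹ and per-cell consumption 2 (normal) / 4 (cancer) min⁻¹,
giving a diffusion–consumption length $\sqrt{D/k} \approx 110$ µm
(roughly three lattice steps) — the scale that makes tissue more than a
few cell layers from a vessel hypoxic, which drives the whole narrative.
Concentrations are normalised so fully oxygenated blood
($H = H_{ref} = 0.45$) has $c_{blood} = 1$. Perfused segments exchange
oxygen transmurally at rate $P_{O2}\, k_A (c_{blood} - c_{tissue})$ with
$k_A = \sigma\, 2\pi R L / V_{site}$; the dimensionless scale
$\sigma = 1/15$ fixes the unit of the permeability coefficient $P_{O2}$ so
that its reference value 3800 places vessel-adjacent tissue near the
quiescence threshold — the regime in which reducing $P_{O2}$ to 3116
(mimicking a vascular-targeting agent) visibly tips cells into quiescence.
The exchange term enters the linear system implicitly (sink coefficient
plus constant source), preserving diagonal dominance and the maximum
principle. VEGF mirrors oxygen with roles swapped: hypoxic or quiescent
cells secrete at a constant rate, perfused vessel sites absorb
(coefficient 1 min⁻¹), and the field decays at 0.05 min⁻¹.

**Solvers.** The flow systems use a direct sparse factorisation; the field
systems use an iterative Krylov method with Jacobi preconditioning at
relative tolerance $10^{-8}$, warm-started from the previous step. The
assembled field systems are symmetric positive definite, so the default
Krylov iteration is conjugate gradients; a restarted GMRES implementation
with identical tolerance semantics is provided for general systems and as
a cross-check (both are verified against dense direct solves on random
instances to $10^{-8}$). On the hot path the matrix is applied matrix-free
through a stencil operator (six vectorised neighbour gathers); its
equivalence with the explicitly assembled sparse matrix is pinned by
tests.

# Cells

Each cell carries a cycle phase $\varphi \in [0, 1)$, p53 and
intracellular-VEGF levels, a status (cycling/quiescent) and a quiescence
clock. The subcellular closure is deliberately minimal — a phase variable
plus linear ODEs with oxygen-switched coefficients — because the contract
that matters at tissue scale is: oxygen shortens the cycle, hypoxia raises
p53 and VEGF, prolonged hypoxia kills. A full protein-network ODE system
can be plugged in behind `subcellular_step()` without touching the engine.

* **Cycle**: $\varphi$ advances by $\Delta t / T_{cycle}(O_2)$,
  $T_{cycle} = T_{min}(O_2 + c_\varphi)/O_2$ ($T_{min}$ = 1600 min cancer,
  3000 min normal; $c_\varphi = 0.1$). At $\varphi = 1$ the cell attempts
  division: the daughter is placed uniformly at random on the mother's
  site or a face neighbour with spare capacity; with no capacity the
  division defers (contact inhibition).
* **Quiescence** (cancer only): while $O_2$ is below the entry threshold
  0.10 a cycling cell arrests with hazard `q_arrest_rate = 0.023` min⁻¹
  (~50% per step) — arrest is checkpoint-like and asynchronous across a
  population, not a synchronous switch; this matters for the elimination
  statistics, where the order in which cells arrest is part of the
  stochasticity. Quiescent cells freeze $\varphi$, secrete VEGF, and die
  when their clock exceeds `t_quiesce_max = 600` min; re-oxygenation above
  the exit threshold 0.12 resumes cycling immediately.
* **p53**: $\dot p = a - \left(b_0 + b_1 \frac{O_2^2}{O_2^2 +
  c^2}\right) p$ with $a = 0.03$, $b_0 = 0.005$, $b_1 = 0.3$, $c = 0.08$.
  The Hill-2 degradation switch gives a high hypoxic fixed point ($a/b_0 =
  6$) and a low normoxic one (~0.1), so cells below $O_2 \approx 0.04$
  cross the death threshold within about an hour. A normal cell dies when
  p53 exceeds a threshold that drops from 0.5 to 0.1 when cancer occupies
  its site or a face neighbour — the mechanism by which a surviving tumour
  erodes the surrounding tissue.
* **Coefficients are constant within a macro step**, so the linear ODEs
  are advanced with their exact exponential solution, vectorised over all
  cells — exact at any step size, and far cheaper than a per-cell adaptive
  integrator.
* **VEGF secretion** is a constant rate (0.04 conc min⁻¹) while the cell
  is quiescent or below its kind-specific onset threshold: 0.08 for
  cancer, 0.03 for normal cells — cancer cells need a lesser degree of
  hypoxia to secrete, and consume twice the oxygen.
* **Movement**: with probability `p_move = 0.1` per step a cell moves to a
  face neighbour sampled with weight proportional to free capacity (with
  capacity 1, uniform over empty neighbours).

# Scenarios and the experiment layer

`init_state()` builds the initial condition: straight parent vessels on
lattice lines filled with normal cells, an optional cancer cube implanted
by replacement, flow/haematocrit/fields solved once.

* **Countercurrent pair**: two parallel vessels along x at one third and
  two thirds of the z-extent, equal mean pressures (25 mmHg), equal and
  opposite 10 mmHg drops. `tiled_pairs` replicates the pair N times along
  y; the implant is replicated per tile in the elimination studies.
* **Eight-vessel unit**: 8 parallel vessels on a 2 (y) × 4 (z) grid with
  equal drops and four distinct mean pressures (20/25/30/35 mmHg) arranged
  so every vessel's nearest neighbour has a different mean — the layout
  designed to sustain inter-vessel connections; `tiled_units` tiles it.
* **Imported network**: any node/edge table in the interchange format
  (`x_um, y_um, z_um, role, pressure_mmhg, inflow_haematocrit`; edges
  `a, b, radius_um`). Nodes snap to the nearest lattice site; edges longer
  than one step are subdivided along a deterministic axis-ordered
  staircase (x, then y, then z); duplicates merge; the import validates by
  solving flow. `synthetic_network_fixture()` generates irregular
  connected 3D graphs with prescribed inlet/outlet counts as stand-ins for
  microscopy-derived networks (no such network is publicly deposited); the
  packaged example under `inst/extdata/` is labelled synthetic
  accordingly.

The experiment layer supplies percentile-bootstrap confidence intervals
for ensemble means (`bootstrap_mean_ci()`, default B = 2000; a
high-precision simulation puts its true coverage for an n = 30 normal
sample at 0.934 ± 0.004 — the familiar slight undercoverage of the
percentile method at small n), trajectory ensembles with pointwise bands
(`ensemble_summary()`; the long-time value is the mean over the final 10%
of each trajectory), and the elimination study.

## Tumour elimination and extrapolation

A tumour counts as **eliminated** when the number of non-quiescent cancer
cells reaches zero at or before the horizon $T_\theta$, and as survived
when the count stays positive throughout — quiescent stragglers are doomed
unless re-oxygenated. If the N subdomains of a tiled domain behaved
independently, the elimination probability would extrapolate as $P_N =
P_1^N$; `elimination_study()` estimates both sides with seed-paired
ensembles and bootstrap CIs across domain sizes and hostility levels
(hostility = reduced oxygen permeability, the printed pairing being 3800 →
3116).

The studies run in a regime chosen on physical grounds: the implant sits
in the hypoxic band between the vessels, so nearly all its cells arrest
within hours and the outcome is a race between the 600-min quiescence
clock and local re-oxygenation as the surrounding normal cells die and
stop consuming. $T_\theta$ defaults to 14 days; the desk-scale studies use
36–48 h, several times the decision timescale of that race, on 10³
lattices.

# What the synthetic scenarios do and do not emulate

The generator-built scenarios reproduce the *structure* of the modelled
biology — parallel parent vessels, countercurrent flow, tiled tissue
units, irregular vascular graphs, hypoxia-driven growth and angiogenesis —
at desk scale (10³–20³ sites, i.e. 0.4–0.8 mm boxes, horizons of days).
They do not emulate: real microvascular morphometry (segment length and
radius distributions), interstitial or intravascular pressure coupling to
tissue stress, pulsatility or non-Newtonian transients, lymphatics, or
immune/stromal populations. Passing tests therefore validate the
implementation and its conservation laws and qualitative regimes, not
quantitative agreement with any particular in vivo tumour.

# Numerical choices and degenerate inputs

* Field solves: rtol $10^{-8}$, iteration cap $10N$; failure to converge
  is an error, never a silent result. Tiny negative concentrations (below
  solver tolerance) are clamped to zero; larger ones abort.
* Flow: direct sparse LU; components without a prescribed-pressure node
  are an error in direct calls and zero-flow/unperfused inside the engine
  (`on_floating = "zero"`), where pruning can transiently orphan
  sub-networks that the low-flow clock then removes.
* Ties and ordering: cells update in stable id order; sprout-initiation
  draws scan eligible sites in lexicographic order; tip paths may revisit
  sites, and path splicing skips self-loops and duplicate segments.
* Degenerate axes (extent 1) carry no flux and offer no moves; an empty
  domain is a fixed point of the step map.
* The pruning clock removes a segment when it *reaches* `t_prune`, making
  "fully pruned after $\lceil t_{prune}/\Delta t\rceil$ steps" exact.

# Known limitations

* Pure-R engine: practical lattice sizes are ~20³–30³ sites for
  interactive work; the field solve dominates runtime (Jacobi-CG iteration
  count grows with domain size).
* The positive wall-shear feedback under fixed boundary pressures makes
  individual radii bistable between the clamps; realistic radius
  *distributions* are outside scope.
* Haematocrit splitting ignores phase separation; arterio-venous identity
  and absolute-pressure-dependent remodelling are not modelled, which is
  also why triply-periodic domains (periodic along the parent-vessel axis)
  are not offered: prescribing periodic pressures along the flow axis is
  ill-posed without tracking wrap counts.
* The subcellular closure is a two-ODE caricature; it is pluggable, and
  only its interface contract (oxygen-dependent cycle speed,
  hypoxia-driven p53/VEGF accumulation, threshold death) is relied on
  elsewhere.

# Reduced problem sizes used by the test-suite

The acceptance-style checks run on: 50 random ≤12-node networks (flow
oracle), 20 random 8³ field instances plus closed-form profiles, a 6³
exhaustive boundary-condition sweep, 5 × 200-step conservation runs on
20³, 10⁴-draw angiogenesis ensembles, 100 + 100 realisation elimination
ensembles on 10³ (and its N = 2 coupling), 48 seed-paired hostility
realisations, and a ~400-step growth-narrative run on 16 × 8 × 16. These
sizes are the package's chosen desk scale: large enough for the laws and
orderings under test to be resolved, small enough to run routinely.
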