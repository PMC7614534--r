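---
title: "Models and methods behind tissuesim"
author: "tissuesim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tissuesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

tissuesim is a two-dimensional multicellular tissue simulator that implements
five discrete cell-based modelling frameworks behind a single simulation
loop. The point of holding all five in one package is comparability: the same
initial condition, cell-cycle machinery, hooks, seed and output format can be
exercised under different physical representations of a cell, so differences
between results can be attributed to the modelling framework rather than to
incidental implementation choices. This vignette states each model precisely,
lists the tunable parameters with their defaults and the reasoning behind
them, documents the numerical conventions, and is explicit about what the
built-in synthetic initial conditions do and do not probe.

Throughout, length is dimensionless with one cell diameter as the unit, and
time is in arbitrary simulation units; all coordinates are planar.

## The five frameworks

### Vertex model (VM)

Each cell is a polygonal element of a shared mesh: elements are ordered,
counter-clockwise rings of node indices, interior edges are traversed in
opposite directions by their two incident elements, and nodes carry the
dynamical state. The tissue energy is

$$U = \sum_i \tfrac{K_A}{2}\,(A_i - A^{0}_i)^2
    + \sum_i \tfrac{K_P}{2}\,P_i^2
    + \sum_{e} \gamma_{\tau(e)}\,\ell_e,$$

area elasticity plus perimeter contractility plus a typed line tension:
$A_i$, $P_i$ are the area and perimeter of element $i$, $A^0_i$ the cell's
target area, $\ell_e$ an edge length, and $\gamma$ a symmetric matrix indexed
by the ordered-free pair of cell types flanking the edge, with a dedicated
index for the tissue boundary ("medium"). This functional is the standard
choice in which *differential adhesion* is literally a matrix entry: setting
the heterotypic tension $\gamma_{AB}$ above the homotypic mean
$(\gamma_{AA}+\gamma_{BB})/2$ makes mixed interfaces energetically expensive
and drives cell sorting. Nodes move by overdamped forward Euler,
$x \leftarrow x + (\Delta t/\eta)\,F$, with the force computed as the exact
analytic gradient $F_j = -\partial U/\partial x_j$ (area gradients via
adjacent-vertex cross products, perimeter and tension gradients via unit edge
vectors); the test suite verifies the analytic gradient against central
differences on random configurations to a relative error below $10^{-5}$.

Topological moves keep the mesh well-formed as it deforms:

* **T1 swap.** When an interior edge falls strictly below the threshold
  `d_t1`, the two elements sharing it lose it, the two elements flanking its
  endpoints gain it, and the two nodes are repositioned perpendicular to the
  old edge through its midpoint at separation
  `t1_separation_ratio * d_t1`. Checks run once per step in ascending
  (node-pair) edge order, at most one swap per node per step, which makes
  event processing deterministic. Swaps that would push an element below
  three nodes, or whose edge is not flanked by four distinct elements (a
  boundary edge), are skipped and counted rather than attempted.
* **T2 removal.** A triangular element with area below `a_t2` collapses to a
  single node at its centroid; neighbours are rewired through the new node
  and the associated cell leaves the population. Non-triangular small
  elements are left to prior T1s.
* **Division.** A division-ready cell's element is split by the line through
  its centroid along the shortest principal axis of its area second-moment
  tensor (or an explicit axis). Cut points landing on existing vertices are
  reused; otherwise new nodes are inserted and shared with the neighbouring
  element across each cut edge so the shared-edge invariant survives.
  Degenerate splits (fewer than two boundary crossings, a daughter below
  three nodes) defer the division by one step.

### Cellular Potts model (CP)

Cells are sets of lattice sites; site `0` is the medium. The Hamiltonian is

$$H = \sum_s \lambda_A\,(A_s - A^0_s)^2
    + \sum_{\langle i j\rangle} J_{\tau(\sigma_i),\tau(\sigma_j)}\,
      [\sigma_i \neq \sigma_j],$$

with each unordered neighbouring site pair counted once and medium sites
using the medium type index. Dynamics are Metropolis copy attempts: a
uniformly random site and a uniformly random neighbour are drawn; if their
cell ids differ, the source id is copied onto the target with probability
$\min(1, e^{-\Delta H/T})$. $\Delta H$ is computed locally over the target
site's neighbourhood, which equals the global recomputation exactly (an
identity the tests assert on random proposals). One time step is
`sweeps_per_step` times the site count in attempts, with incremental area
bookkeeping; cells reduced to zero sites are removed. The default interface
neighbourhood is Moore (8 neighbours): with von Neumann connectivity the
interface energy over-rewards axis-aligned boundaries. Cell connectivity is
*not* enforced — a cell may fragment at high temperature; this is documented
behaviour, not an error. No division move is defined for CP cells; CP
scenarios are division-free and scenario validation rejects a proliferative
cycle model there.

### Cellular automaton (CA)

At most one cell per site. Cells are visited in random order each step; with
probability `motility` a cell moves to a uniformly chosen vacant neighbour
(von Neumann by default), staying put when none is free. Division places a
daughter in a uniformly chosen vacant neighbour and is deferred while none
exists. Exclusion is absolute, so a fully occupied lattice is frozen. A
single free cell with `motility = 1` performs an unbiased lattice random
walk, giving the diffusive benchmark $\langle r^2\rangle = n$ after $n$
steps that the acceptance suite measures.

### Cell-centre models (PM and VT)

Each cell is a point. Neighbours are either all pairs closer than a cutoff
(overlapping spheres, PM; default cutoff 1.5 rest lengths) or pairs sharing
a Delaunay edge (Voronoi tessellation, VT). Each neighbour pair interacts
through a linear spring, force magnitude $\mu(|r_{ij}| - s_{ij})$ along the
centre line, attractive when stretched and repulsive when compressed — the
simplest member of the generalised-spring family and the canonical
cell-centre baseline. After a division the sibling pair's rest length ramps
linearly from `newborn_separation` to the mature rest length over
`growth_duration`, after which the registry entry expires and the pair is
indistinguishable from ordinary neighbours. Positions follow the same
overdamped Euler update as the vertex model. Two relaxing cells obey
$d(t) = s + \delta_0 e^{-2\mu t/\eta}$ exactly in the continuum limit, which
the tests match to 1% at $\Delta t = 10^{-3}$. VT mode uses unrestricted
Delaunay edges; distant boundary cells can therefore acquire spurious
neighbours (a known limitation of the unpruned dual), and writers export the
box-clipped Voronoi polygons so VT output is visually comparable with VM
output.

## Geometric kernel

Polygon measures are shoelace-based; rings are stored counter-clockwise and
clockwise input is repaired by reversal, while self-intersections are
reported as errors rather than silently fixed. Delaunay triangulation is
Bowyer–Watson point insertion with a determinant in-circumcircle predicate;
for four cocircular points either diagonal may be returned, both being valid
tessellations (the tie has measure zero and tests avoid exact cocircularity
by construction). Voronoi regions are built by half-plane clipping of the
bounding box against every perpendicular bisector: unbounded regions are
always clipped, never dropped, so the regions partition the box to
$10^{-9}$ relative tolerance — a property the tests assert. Mesh validity
enforces a node-merge tolerance of $10^{-10}$ (relative to edge length 1).
The honeycomb generator builds pointy-top hexagons in offset rows and
deduplicates shared nodes by rounding coordinates (in units of the edge
length) to $10^{-6}$, far below the node spacing of half an edge; the
construction details (offset parity, no boundary trimming) follow common
convention.

## Cell cycle models

Three kinds cover the usual repertoire:

* `fixed`: deterministic G1/S/G2/M durations; division when age reaches
  their sum, independent of the step partition (within one step).
* `uniform`: G1 drawn once per cell from U(`g1_min`, `g1_max`) at creation
  — not at query time — so replaying a run redraws identical values.
* `contact_inhibited`: as `uniform`, but G1 progress pauses while the cell's
  current area is below `quiescent_area_fraction` of its target area; the
  arrested time extends the cycle, so a perpetually compressed cell never
  divides.

Daughters inherit type and target area, are born at the division time with
fresh ids, and redraw G1 independently. Divisions within a step are
processed in ascending cell id, and a cell divides at most once per step.

## The simulation loop, reproducibility, and output

Per step, in fixed order: mechanics (forces and the Euler update, or the
lattice sweep), topological events (all T1 checks then T2 checks), cell-cycle
advance and divisions/removals, modifiers in declared order, then writers at
sampling steps. This ordering is a convention of this package, stated here
because it is observable: permuting the declared modifier order is the only
sanctioned source of order dependence. A single global RNG stream is seeded
from the scenario and consumed in the loop's fixed phase order, which makes
identical scenarios replay byte-identically (asserted by hashing frames);
the flip side, also by design, is that disabling one phase (say, noise)
shifts the draws of later phases, so replay stability across *different*
scenarios is not guaranteed.

Output is plain inline-ASCII XML VTU frames plus a PVD index — loadable in
ParaView and colourable by the integer cell-data array named exactly
"Cell types" — with a CSV metric series and a JSON manifest echoing the
fully resolved scenario, so every run is self-describing. ASCII rather than
binary-appended VTU trades file size for bit-stable diffs and maximal reader
compatibility, the right trade at the problem sizes this package targets.
Writers never mutate state; a crashed run leaves a valid truncated series.

## Parameters that matter, and defaults

| parameter | meaning (units) | default | why |
|---|---|---|---|
| `k_area` | VM area stiffness (energy/length^4) | 50 | stiff areas, the dominant restoring term |
| `k_perimeter` | VM contractility (energy/length^2) | 1 (0.05 in sorting) | sorting needs tension contrast to dominate |
| `gamma` | VM line tension matrix (energy/length) | 0.1; sorting: AA=BB=0.5, AB=4, medium=2 | heterotypic above homotypic mean drives sorting |
| `d_t1`, `t1_separation_ratio` | T1 threshold and post-swap spacing | 0.05, 1.5 | small vs edge length 1; >1 prevents immediate re-swap |
| `a_t2` | T2 area threshold (length^2) | 0.01 | well below a healthy cell area of ~2.6 |
| `noise` | VM nodal noise per step (length) | 0 (0.02 in sorting) | escapes local minima; off unless asked for |
| `lambda_area`, `temperature` | CP area stiffness, Metropolis T | 1, 1 (sorting: T=2) | boundary fluctuations without cell evaporation |
| `adhesion` | CP contact energies | sorting: AA=BB=2, AB=11, medium=16 | J_AB > mean homotypic; large medium J keeps the blob cohesive |
| `motility` | CA move probability per step | 1 | the pure exclusion walk |
| `stiffness`, `cutoff` | centre spring constant, PM radius | 15, 1.5 | canonical baseline; cutoff excludes next-nearest shells |
| `newborn_separation`, `growth_duration` | daughter spacing and ramp (length, time) | 0.3, 1 | gentle post-division relaxation |
| `dt` | time step | 0.01 (0.002–0.005 for VM) | see stability below |

The sorting parameter sets were calibrated once, when the scenarios were
designed, to give robust sorting on the default geometries; they are design
choices of this package, not canonical values from any reference
implementation, and are stored in the bundled scenario definitions where a
user can read and override every one of them.

## Numerical choices

**Stability bound.** Forward Euler on the vertex model is conditionally
stable: the stiffest mode is the area term, with an effective rate of order
$K_A A^0/\eta$. For the default monolayer set ($K_A=50$, $A^0\approx 2.6$,
$\eta = 1$) the documented stability bound used by the relaxation scenarios
and tests is $\Delta t = 0.002$, at which a 500-step relaxation of a
perturbed honeycomb has a strictly non-increasing energy series; the sorting
scenario runs at $\Delta t = 0.005$ with noise, where monotonicity is
neither expected nor asserted.

**Thresholds and ties.** T1 comparison is strict (`<`); an edge exactly at
`d_t1` does not swap. Cocircular Delaunay ties accept either diagonal. The
short-axis division direction is the eigenvector of the smaller second-moment
eigenvalue; for shapes with an isotropic moment tensor (a regular hexagon)
the eigen-solver's deterministic choice is used. Coincident cell centres
(separation below $10^{-12}$) repel along a random direction rather than
producing an infinite force.

**Degenerate inputs.** Rings with fewer than three points, zero-area rings,
collinear point sets for tessellation, discs that do not fit their lattice,
and scenarios whose sampling interval is not a positive multiple of `dt` are
rejected with typed conditions; scenario validation reports *all* violations
at once rather than the first.

## What the synthetic initial conditions emulate — and what they do not

The generators produce the study conditions of the bundled scenarios: a
regular honeycomb (the standard relaxed-monolayer starting point for vertex
models), a disc of balanced, 4-connected Potts domains or scattered CA
cells, and uniform random point clouds for centre models. Cell types are
assigned by independent coin flips. These are idealisations: real epithelia
have disordered polygon class distributions, correlated type patterns,
boundary effects and heterogeneous cell sizes, none of which the generators
reproduce. Consequently, a passing suite shows that each framework's
*mechanics and statistics* behave as its model prescribes (gradient
consistency, Boltzmann acceptance, diffusive scaling, closed-form
relaxation, monotone sorting) — it does not show that any parameter set
quantitatively reproduces a particular biological tissue.

Problem sizes in the tests were chosen as the smallest that exercise every
code path with stable statistics: 6x6-cell sorting meshes over five seeds,
30x30 Potts lattices with ~12 cells, $10^3$ random-walk replicates, $10^5$
Metropolis trials per calibration point, and 8–12-point tessellations against
an $O(n^4)$ brute-force oracle.

## Known limitations

Strictly two-dimensional; no periodic boundaries (lattice edges simply have
fewer neighbours, meshes have free boundaries); no boundary (T3)
element–node collision handling, so vertex scenarios should keep tissues
simply connected; no CP division move and no CP connectivity constraint; VT
neighbour graphs are unpruned Delaunay; no subcellular reaction networks; no
checkpointing or parallel execution. The command line is a thin wrapper —
`inst/cli/tissuesim run|demo|validate` — and everything it does is available
programmatically.
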