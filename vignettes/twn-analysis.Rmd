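---
title: "Topological water network analysis: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological water network analysis: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twnr)
```

## The model

Water inside a binding pocket is not a featureless continuum: snapshots of
explicit-solvent MD show short-lived but recurring *rings* of 3–6 waters
held together by hydrogen bonds — topological water networks (TWNs). Where
such rings persist across frames, the protein environment stabilises
structured water, and a ligand that places a hydrogen-bonding group there
can pick up the interactions the water enjoyed. `twnr` turns that idea into
a measurable pipeline: detect the rings, attribute them to regions of a
reference ligand, and quantify how much of the ligand's shape the ring
ensemble covers.

### Pair energetics

The hydrogen-bond decision is energetic, not geometric. For two rigid
3-site waters $a$ and $b$:

$$v(a,b) = \sum_{i \in a}\sum_{j \in b} \frac{k\, q_i q_j}{r_{ij}}
  + \frac{A}{r_{OO}^{12}} - \frac{C}{r_{OO}^{6}}$$

* Coulomb over all nine site pairs; Lennard-Jones on the O–O distance only.
* Defaults ($A = 582\,000$ kcal·Å¹²/mol, $C = 595$ kcal·Å⁶/mol,
  $q_O = -0.834\,e$, $q_H = +0.417\,e$) are the classic empirical liquid
  water parameterisation these ring analyses are calibrated against.
* $k$ is the electrostatic conversion constant. The potential is stated with
  an explicit $e^2$ factor and no conversion; the only value that makes the
  −2.25 kcal/mol criterion sit "near the minimum of the pair energy
  distribution" in these units is the standard
  $k = 332.0636$ kcal·Å·mol⁻¹·e⁻², which is what `potential_params()`
  defaults to (overridable).
* Two waters are bonded when $v \le -2.25$ kcal/mol. The comparison is
  inclusive (`<=`): the boundary case is measure-zero in real data, and
  fixing it keeps every downstream result deterministic.
* These charges are applied regardless of the water model that generated
  the trajectory (trajectories are often run with a different 3-site
  model); the criterion is a *scoring* convention, not a simulation one.
  Both charges and threshold are config keys.

A canonical linear hydrogen-bond dimer (O–O 2.8 Å, rigid O–H 0.9572 Å,
H–O–H 104.52°) evaluates to −6.175 kcal/mol — comfortably below the
threshold; at 30 Å separation the interaction decays below 0.2 kcal/mol.
Both behaviours are pinned by tests against an independent term-by-term
summation.

### Periodic boundaries

Frames may carry an orthorhombic box. Minimum-image displacement is
computed once per water pair from the O–O vector, and that single lattice
shift is applied to all nine site pairs, keeping each molecule rigid —
molecules are never split across a boundary. Hydrogens are also unwrapped
to their oxygen's image at parse time. Whether imaging applies during
analysis is simply whether the frame has a box; both modes are supported
because trajectory post-processing conventions vary. Triclinic boxes are
rejected rather than silently mishandled (the systems this targets are
cubic).

### The hydrogen-bond graph and ring definition

Per frame, nodes are waters and edges are bonded pairs. Candidate pairs are
limited to O–O ≤ 3.5 Å by a cell-list spatial index; at larger separations
the pair energy cannot reach −2.25 kcal/mol, a claim the test suite checks
empirically by comparing the prefiltered graph with the exhaustive
all-pairs graph on liquid-density boxes (they must be identical).

A **ring** is a *chordless* simple cycle of length 3–6. The alternative —
all simple cycles — would count the perimeter of two fused triangles as an
additional 4-ring. Chordless cycles match chemical ring perception and
avoid double counting; because the raw ring-size distribution is not
otherwise anchored, the choice is documented rather than hidden, and
`enumerate_rings(..., all_cycles = TRUE)` exposes the other convention for
sensitivity analysis. Enumeration anchors each cycle at its smallest
member, walks only higher-indexed vertices, prunes chords as it extends,
and reports each ring once in canonical order (smallest member first, then
its smaller neighbour), so output is independent of edge input order.

### Ring centers and region attribution

A ring's center is the unweighted centroid of its member **oxygens**:
oxygen carries 16/18 of a water's mass, so the hydrogens add little beyond
orientation noise. Full mass weighting (16:1:1 over all sites) is available
via `weighting = "mass"`. With a box, members are unwrapped to the first
member's image before averaging.

Analysis is restricted to waters within a site sphere (default radius
25 Å), centered on the reference-ligand centroid unless an explicit center
is given. A ring is attributed to the region (head/linker/tail) of the
*nearest labelled ligand atom*, accepted only within a cutoff (default
5 Å; a 3–7 Å sweep is a one-liner around `occupancy_report()`). Exact ties
resolve by priority L′ > linker > head > tail. Whether "near the carbonyl"
means a sub-partition of the linker or a distance criterion is not
decidable from the aggregate percentages alone; `twnr` implements it as a
sub-flag: a linker ring is additionally marked L′ when its center lies
within `lprime_cutoff` (default: the assignment cutoff) of an L′ atom.

Occupancy percentages are computed over *assigned* rings only, pooled over
frames (each ring instance counts once per frame it appears in). The
assigned-only denominator is deliberate: the head/linker percentages this
mirrors sum to 100 with no tail contribution, implying a split over
site-proximal rings that were actually found.

### Shape similarity

The geometric comparison lives on a boolean voxel grid (default spacing
0.5 Å). Ligand voxels are those within the element's Bondi van der Waals
radius of an in-scope atom; TWN voxels are within 1.4 Å (a water probe) of
any member oxygen of any ring that survived proximal extraction (center
within 2.0 Å of a ligand heavy atom — measured to the nearest heavy atom,
not the ligand centroid, which would exclude nearly everything). The
default score is **coverage**: the percentage of ligand (or region) voxels
also occupied by TWN density. Coverage reproduces the expected qualitative
pattern — a hydrophobic tail with no rings drags the whole-ligand score
down while a hydrated L′ region scores high — and is monotone under added
rings. The exact historical formula behind published similarity numbers is
not restated in the aggregate report this design follows, so a symmetric
Tanimoto mode (`mode = "tanimoto"`) is shipped alongside, and the default
is documented as an interpretation rather than a reproduction.

## What the synthetic generator emulates — and what it does not

`make_ring()` places oxygens on a regular polygon with 2.8 Å edges; each
water donates along the edge to its clockwise neighbour and its free
hydrogen lies in-plane pointing radially outward. This symmetric geometry
was chosen because it satisfies, for every size 3–6, the postcondition the
generator *verifies at build time* against the actual potential: adjacent
pairs bonded (≤ −3.5 kcal/mol in practice), non-adjacent pairs not
(≥ −1.9 kcal/mol). Coupling fixtures to the real energetics means a future
change to the potential that breaks ring detection fails loudly in the
generator, not silently in the statistics.

`plant_scene()` builds multi-frame scenes with known ground truth: at most
two rings per frame, offset perpendicular (±y) from cycling anchor atoms of
their target regions at 4 Å (non-L′ linker rings use 4.9 Å so their centers
stay outside the default L′ sub-flag cutoff — the generator re-derives each
planted ring's assignment and refuses to emit a scene whose truth would be
ambiguous). Because ring planes are perpendicular to the offset, rings in
opposite slots keep all oxygens ≥ 8 Å apart, guaranteeing isolation for
any size mix. Noise waters are rejection-sampled to stay beyond the H-bond
prefilter from every ring oxygen and from each other, so they can neither
form nor join rings. The toy ligand is a 12-atom rod (4 head, 4 linker with
a mid-linker carbonyl oxygen as L′, 4 tail) at 1.5 Å spacing.

Passing planted-truth tests therefore shows the *machinery* is exact:
counts, sizes, regions, percentages and boundary conventions are recovered
without error. It does **not** show that real pocket water forms such
rings — planted scenes have ideal geometry, no thermal disorder, no
protein, and liquid-like noise is deliberately kept ring-free. Conclusions
about a real system still require a real trajectory.

## Numerical choices and degenerate inputs

* O–O below 0.1 Å is an error (overlapping molecules), as is a water
  without two hydrogens or O–H bond lengths outside 0.5–1.5 Å at parse
  time.
* Empty frames give empty graphs, not errors; an empty site selection
  warns; a scene with zero assigned rings sets an explicit
  `no_assigned_rings` flag and reports percentages as zero rather than NaN.
* Boundary comparisons are inclusive throughout (site radius, assignment
  cutoff, proximal cutoff, H-bond threshold).
* Grid congruence is required exactly; similarity between grids with
  different origins/spacings/dims is an error, never a silent resample.
* All stochastic generators take a seed and restore the caller's RNG
  state.

## Problem sizes

The test suite and acceptance script are sized for a laptop-class run:
1000 random dimers against the summation oracle, 50 boxes of 100 waters
for the prefilter-vs-exhaustive identity, 200 random graphs (n ≤ 12)
against the subset oracle, and a 1000-ring / 500-frame planted occupancy
scene. The full suite runs in well under a minute per file; the same code
scales to the hundreds of frames and thousands of site waters typical of a
10 ns pocket trajectory, where the cell-list prefilter keeps graph
construction near-linear in water count.

## Known limitations

* Only orthorhombic boxes; only 3-site waters (no polarizable or 4/5-site
  models); no geometric distance–angle H-bond criterion.
* No binary trajectory formats (XTC/DCD) — convert to GRO/PDB first.
* No thermodynamic scoring of hydration sites and no ring-lifetime
  kinetics; rings are counted per frame, not tracked across frames.
* Shape similarity is voxel-based; scores carry a discretisation
  tolerance of a few points under rigid rotation (tested < 3 points), and
  the coverage convention is an interpretation, as discussed above.
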