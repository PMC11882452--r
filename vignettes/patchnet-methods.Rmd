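---
title: "Patchy-disc simulation and network morphology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patchy-disc simulation and network morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# chunks are displayed, not executed: the examples below are full-scale
# simulations that take minutes to hours
knitr::opts_chunk$set(eval = FALSE)
```

patchnet simulates the two-dimensional self-assembly of trisymmetric
macromonomers — DNA three-point-star (3PS) tiles adsorbed on mica are the
motivating system — and quantifies the resulting networks with the same
observables used for AFM images: island statistics, polygon census,
network density and border ratio. This vignette records the model, the
meaning and defaults of every tunable parameter, the numerical choices,
and the limits of what the synthetic benchmarks can show.

## The model

A monomer is a hard disc of diameter $\sigma$ (the length unit) carrying
three attractive patches at 120°. Two particles $i,j$ interact through a
state-augmented Kern–Frenkel potential: the pair energy is $-\varepsilon$
when

1. $\sigma \le r_{ij} < \sigma + \delta$ (square-well shell),
2. a patch on each particle points at the partner within the half-opening
   angle $\theta_{pw}$ (i.e.
   $\cos\angle(\hat n_\alpha, \hat r_{ij}) > \cos\theta_{pw}$ on both
   sides), and
3. both patches are in their *closed* state ($p = 1$).

and zero otherwise ($r_{ij} < \sigma$ is a hard rejection). The binary
patch state models interface flexibility: a closed interface (arms
parallel) can stack, an open one (arms splayed) cannot. States flip
through a dedicated Monte Carlo move with acceptance
$\min(1, \frac{w_{\mathrm{new}}}{w_{\mathrm{old}}} e^{-\Delta E})$, where
$w(\mathrm{open}) = P_{\mathrm{open}}$ and
$w(\mathrm{closed}) = 1 - P_{\mathrm{open}}$. This is the minimal
detailed-balance-respecting coupling for which an *isolated* patch is
open with stationary probability exactly $P_{\mathrm{open}}$ — the
model's interface-flexibility knob.

Defaults follow the physical system: $\sigma = 1$, $\delta = 0.038$ (a
~0.45 nm stacking range on a ~12 nm tile), $\theta_{pw} = 0.44$ rad,
$\varepsilon$ in units of $k_BT$ ($\beta \equiv 1$). The constructor
enforces $\theta_{pw} < \arcsin\!\big(\sigma / (2(\sigma+\delta))\big)$,
which guarantees geometrically that one patch can never satisfy the
angular criterion with two partners at once (single bond per patch), and
$\theta_{pw} < \pi/3$ so patches do not overlap on the perimeter.

Adsorption to the substrate is represented as strict two-dimensional
confinement in a periodic square box; there is no explicit substrate
energy term. Where the density is not dictated by a protocol we default
to $N = 200$ particles at area fraction 0.1.

```{r model}
library(patchnet)
p <- model_params(epsilon = 8, p_open = 0.8, n_particles = 150)
tr <- run_mc(p, n_sweeps = 5e5, record_every = 2500, seed = 1)
classify_state(tr)
```

## The sampler

`run_mc()` is a Metropolis sampler with four move classes (default
fractions): single-particle translation (0.4, step 0.3 σ), rotation
(0.2, step 0.4 rad), patch-state flip (0.3), and rigid cluster moves
(0.1). A cluster move selects the bonded component of a random seed with
probability inversely proportional to its size (mimicking size-dependent
diffusivity), proposes a rigid translation or rotation, and rejects any
proposal that would create a new bond or an overlap; within this move
class that rejection rule preserves detailed balance, and because a
cluster is a full bonded component no bond can break either, so accepted
moves cost no energy. Clusters spanning more than half the box cannot be
unwrapped consistently on the torus and such proposals are skipped; for
clusters whose ends approach each other through the periodic boundary the
member–member torus distances are re-checked explicitly. An optional
deposition step inserts Poisson-distributed particles per sweep for
kinetics experiments only.

Step sizes can be tuned once with `calibrate_schedule()` (target 30–50%
acceptance) and are then frozen; production runs never adapt. All
randomness flows through R's RNG: one seed reproduces a trajectory
byte-for-byte. Energies are tracked incrementally and re-derived from
scratch at every recorded frame; the two must agree to $10^{-8} N$.

The default production protocol is $5 \times 10^5$ sweeps recording every
$2.5 \times 10^3$ (200 frames), so the 20-frame classification window is
the last 10% of the run. The test suite uses $6\times10^4$–$10^5$-sweep
versions of the same protocols with one replicate, and the acceptance
script runs its scan at $2.5\times10^5$ sweeps with three replicates per
point; these sizes are the package's chosen balance between sampling and
turnaround and are stated wherever results are produced.

## Morphology observables

The quantification stack mirrors an AFM image-analysis routine:

* **Bond graph** — from a simulation frame, edges are exactly the
  Kern–Frenkel bonds; from a detected point set, edges join pairs closer
  than 1.25× the modal nearest-neighbour distance, with node degree
  capped at 3 by removing the longest edges at over-connected nodes.
  Coordinates are unwrapped per component across the periodic boundary.
* **Islands** — connected components; frame-level statistics use only
  islands of ≥ 24 particles (the statistics-eligibility threshold).
* **Polygons** — faces of the planar embedding, traced with the rotation
  system (neighbours sorted by angle; each half-edge continues to the
  next-clockwise half-edge at its head). The unique walk with the most
  negative signed area is the outer face; simple interior cycles of 3–9
  vertices are polygons, larger or non-simple interior faces are counted
  as voids. Crossing edges (possible in noisy point sets) are resolved by
  deleting the longer edge of each crossing pair, and the island is
  rejected when more than 5% of its edges cross. Euler's identity
  $V - E + F = 2$ is asserted for every traced island.
* **Network density** — $ND = E / E_{\max}(V)$, the island's bond count
  over that of the maximally compact honeycomb island with the same
  particle count. $E_{\max}$ is exact by exhaustive search over connected
  honeycomb subgraphs for $V \le 12$ and by a hexagon-cell spiral
  construction (validated against the exhaustive values) beyond. ND is 1
  exactly for ideal radially grown crystals and falls to
  $(V-1)/E_{\max}(V)$ (≈ 0.72–0.77 for 24–100 particles) for chains and
  trees. Frame summaries are island-size-weighted means over eligible
  islands. The formula sits behind one function so an alternative
  normalizer can be swapped in.
* **Border ratio** — the fraction of an island's polygons with at least
  one vertex on the outer boundary walk (the stricter, unambiguous
  reading of "polygons on a border"); 0 when there are no polygons. It is
  1 for pure-border growth and decreases strictly as full hexagon rings
  are added around a compact core.

## Phase classification

`classify_state()` labels a finished run from its last 20 recorded frames
with mean eligible-island ND as the principal metric and island size as
the secondary determinant: *gas* when the largest island in the window
stays below 24 particles; otherwise *short_like* when the size-weighted
mean ND is at least `nd_cut` (default 0.75) and *long_like* below it; a
*dla* override applies when the dynamics are kinetically trapped
(accepted bond-breaking rate below $10^{-3}$) and the largest island is
large and ramified (border ratio > 0.9 at ≥ 100 particles), the signature
of the diffusion-limited-aggregation limit of very strong attraction.
`nd_cut` is exposed because no published threshold exists; 0.75 sits
between the tree value (≈ 0.77 at the eligibility threshold, falling to
≈ 0.72 at 100 particles) and compact-crystal values (≥ 0.85 in practice).
All thresholds are recorded in the returned object, and classification is
a pure function of the stored window.

`sweep_phase_diagram()` runs a replicate grid over any two model
parameters, derives per-run seeds by a stable integer hash of (master
seed, grid point, replicate), takes majority labels (ties resolved by the
replicate with the median mean-ND), and `locate_boundary()` reports
bracketing grid intervals with their midpoints — never fitted or
extrapolated boundaries, matching the resolution the grid actually has.

## A known limitation: the equilibrium realization versus printed state diagrams

The intrinsic-weight Metropolis coupling has a clean consequence: for any
observable the patch states integrate out, renormalizing the bond
strength to
$\varepsilon_b = \varepsilon + 2\ln(1 - P_{\mathrm{open}})$. The phase
behaviour therefore depends on $(\varepsilon, P_{\mathrm{open}})$ only
through $\varepsilon_b$, producing a single gas-to-compact assembly line
(plus kinetic trapping at very strong coupling) — an *equilibrium*
realization of interface flexibility. Two things follow, which the
acceptance tests make visible rather than hide:

1. The gas-to-assembly onset sits a few $k_BT$ higher in $\varepsilon$
   than the reference state diagrams for this system report: with
   $\delta = 0.038$, bonds of $\varepsilon_b \lesssim 6$ cannot hold a 2D
   crystal at dilute coverage (seeded crystals evaporate), so scans at
   $\varepsilon = 6$ classify as gas throughout and the short-like→gas
   boundary they are meant to bracket does not exist in this realization.
2. Because only $\varepsilon_b$ matters, an equilibrium *elongated*
   (long-like) phase never emerges: whenever bonds are strong enough to
   assemble at all, compact three-valent networks out-compete chains.
   Elongated morphologies of the real system are evidently a signature of
   the state-*switching kinetics* (and possibly substrate adhesion), not
   of the equilibrium ensemble.

The sampler's correctness is established independently of this
discrepancy — the two-particle bonded fraction matches a quadrature
oracle, the open-patch fraction matches $P_{\mathrm{open}}$ at
$\varepsilon = 0$, and bond counts match the dilute-limit association
constant — so the gap is a property of the model realization, not of the
implementation. The state-flip acceptance rule is isolated in one
function should a kinetic (energy-independent resampling) variant ever be
added.

## Synthetic ground truth

`make_compact_island()` grows a disc of fused polygons face by face in a
ring-closing spiral. Each growth step draws a face size from {5, 6, 7}:
pentagons and heptagons are planted at the requested rates as adjacent
5–7 dipoles (the dislocation cores seen in real lattices), which keeps
the net disclination charge zero so the sheet embeds flat. All-hexagon
discs get exact lattice coordinates; defective discs are embedded by a
Tutte embedding (boundary pinned on a circle, interior vertices at
neighbour averages) followed by L-BFGS relaxation of an elastic energy
with bond springs, a soft non-bonded repulsion below 1.5 lattice
constants and per-face signed-area terms that forbid folds. An embedding
is accepted only when every bond is within 10% of the lattice constant
and no non-bonded pair intrudes below 1.3 lattice constants; failing
embeddings restart from perturbed starts, and the rare defect placements
that cannot be embedded flat within tolerance are redrawn, keeping the
recorded ground truth exact. The planted polygon census equals the
morphology stack's output on the noiseless point set — the round-trip
invariant the test suite asserts.

`make_elongated_island()` is a neighbour-avoiding self-avoiding walk on
the honeycomb lattice (with optional branching), so the bonded graph is
exactly a tree: no polygons, border ratio 0 by convention, ND at the tree
value. `make_field()` composes non-overlapping mixtures of compact,
elongated and single-particle components in a field (default 750 nm) with
a 16 nm default lattice constant — not a published number, but chosen so
a 750 nm field holds islands of the apparent scale of this system's AFM
fields; both are exposed.

`rasterize()` renders each monomer as a three-armed Gaussian-ridge star
(arm length half a lattice constant, ridge width 3 nm, height 2 nm — the
apparent DNA height), on a 256-pixel, 750 nm raster (2.93 nm/px) with
additive Gaussian pixel noise (default 0.1 nm) and per-scan-line constant
offsets (default 0.15 nm), the dominant AFM artefact that line-wise
flattening addresses. What the generator does *not* emulate: tip
convolution, drift between frames, multilayer crowding, and partially
formed or deformed monomers — so passing the detection benchmarks shows
the pipeline is correct and noise-tolerant at realistic scan settings,
not that it would meet the same numbers on real micrographs.

## Image analysis

`image_to_morphology()` composes the four analysis stages: (1) per-line
polynomial flattening against background pixels below a robust threshold;
(2) bilinear upsampling to ~1.5 nm/px — at the native 2.93 nm/px the
ridges are only two pixels wide and thinning destroys junctions — then
Otsu thresholding (with a featureless-image guard and a manual override
in nm) and a radius-1 morphological opening; (3) Zhang–Suen
skeletonization with monomer centres at the 3-way skeleton junctions (the
unique junction of the three-armed tile), merged within 0.3 lattice
constants, with blob centroids as the fallback for junction-free
components; (4) the bonded-graph morphology stack on the detected
centres. On synthetic fields at default noise this recovers ≥ 95% of
centres with ≥ 95% precision, and image-side weighted ND tracks ground
truth with rank correlation above 0.9 across field classes.

## Degenerate inputs and tie-breaks

Empty fields, empty masks, single-particle islands (ND defined as 0),
two-particle islands, acyclic islands (border ratio 0), and featureless
images all return well-defined empty results rather than errors. When two
patch pairs could satisfy the bonding criterion simultaneously (excluded
geometrically at the defaults but possible for user parameters near the
bound), the pair with the smallest summed angular deviation wins and the
pair still contributes a single $-\varepsilon$. Majority-vote ties in
sweeps go to the replicate with the median mean-ND. Boundary location
never extrapolates beyond the scanned grid.
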