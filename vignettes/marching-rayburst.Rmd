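---
title: "Tracing neuronal morphology with marching rayburst sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing neuronal morphology with marching rayburst sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rayburst)
```

## The problem

Neurites in light-microscopy image stacks are, at typical resolution,
smooth tubular structures: locally well approximated by a generic cylinder
whose radius and direction change slowly along the structure. A digital
reconstruction represents the neuron as a tree of nodes, each with a
location `C` on the centerline, a unit tangent direction `v`, and a radius
`r` (the minimum distance from `C` to the structure boundary, measured in
the plane orthogonal to `v`). The SWC format serializes exactly this.

rayburst reconstructs such trees by *marching*: from one or a few
user-chosen seed points it alternates a **prediction** step (where does
the structure continue, and does it branch?) with a **refinement** step
(exactly where is the centerline, and how thick is the structure?),
pushing every predicted child into a FIFO queue until the whole tree has
been explored. Only voxels near the current structure are ever touched,
which is what makes the approach fast compared with whole-image
segmentation or skeletonization, and the per-node sampling geometry scales
with the local radius, so the same parameters work across structures of
very different absolute size.

## Boundary detection along rays

All geometric queries reduce to casting rays. A ray walks from its origin
in steps of `step` voxels (default 1.0), interpolating the volume
trilinearly, and stops when its sample is classified *background* by a
two-level hysteresis rule: intensity at or above `high` is foreground,
below `low` is background, and anything in between inherits the previous
sample's class. The band suppresses single-voxel flicker along the ray.
Samples outside the grid are background, so rays leaving the volume
terminate naturally.

In adaptive mode (the default) the two thresholds are recomputed at every
ray-cast batch origin: the local foreground level `F` is the intensity at
the origin, the local background level `B` is the 10th percentile of a
cubic neighborhood of half-width three times the current radius, and

    high = B + 0.5 (F - B),   low = B + 0.25 (F - B).

The coefficients, quantile and neighborhood scale are all configurable in
`boundary_detector()`. Two details are deliberate design choices of this
package. First, thresholds are resolved once per sampling batch (one
hemisphere sample, one refinement pass), not per individual ray step; the
local statistics change negligibly within a batch and the quantile is the
expensive part. Second, an origin whose local contrast `F - B` falls below
`min_contrast` (default 0.05) is declared invalid: with the relative rule
alone, a pure-background origin would have `F` and `B` nearly equal and
every sample would count as foreground. The contrast floor makes
"seed/prediction in background" a well-defined, detectable condition.

## Prediction: hemispherical sampling and branch detection

At a node `(C, v, r)` the tracer must decide where the structure
continues. It casts a precomputed *hemisphere core* of rays — forward only,
to avoid re-tracing where it came from — each capped at
`sampling_distance * r` (default 3, sensible range 2–4). Rays that reach
the cap without hitting the boundary are still inside the structure and
record state 1; the rest record 0.

The core divides the hemisphere into `M = 7` inclination rings at equal
angular spacing from pole (`theta = 0`) to equator (`theta = pi/2`); ring
`k` carries `max(1, 8k)` equally spaced azimuths. This odd-looking
population rule is what makes branch detection simple: the ring
populations 1, 8, 16, 24, ... are exactly the cell counts of concentric
square rings, so the samples map one-to-one onto a `(2M-1) x (2M-1)`
square grid (each inclination circle maps onto its circumscribed square,
azimuth order preserved). The equator is included so branches nearly
perpendicular to `v` remain detectable. For strongly anisotropic stacks
an anisotropy coefficient `epsilon` (about 1.0–1.1) scales the axial
component of each core vector before renormalization, concentrating
samples toward the pole; alternatively `load_volume()` can linearly
super-sample the axial direction.

On the grid, the nonzero cells of a single unbranched tube form one
connected cluster around the pole; a bifurcation ahead splits them into
two clusters. Clusters are labeled with 8-connectivity (cells that are
azimuthal neighbors on a square ring can touch diagonally), and each
cluster's representative direction is the cell maximizing the Euclidean
distance to the cluster's complement — a distance-transform center. Ties
prefer the smaller inclination ring (closer to the current direction,
which damps zig-zag), then the smaller azimuth slot. Each center, mapped
back through the grid bijection and rotated into the world frame, becomes
a predicted child at `location_distance * r` from the node (default 2
radii, i.e. one diameter), with the parent's direction and radius as the
initial guess.

## Refinement: iterative 2D rayburst

Predicted nodes are imperfect: the location may be off-center and the
radius is inherited. Refinement casts `N = 32` rays uniformly in the plane
orthogonal to the current direction, collects the boundary intersections,
and moves the origin to their centroid — exact for an elliptical
cross-section, a contraction toward the center in practice. The iteration
exits when successive origins move less than `0.05 r`; the radius is then
the mean ray length of a fresh sampling at the converged origin.
Because the refined position changes the local tangent (recomputed as the
unit vector from the parent node, whose segment to the current node
represents the local centerline), the plane itself is re-oriented and the
refinement repeated until successive directions differ by less than
`pi/36` radians.

Numerical guards, all flagged rather than silent: rays are capped at
4 times the radius guess (otherwise rays in confluent regions or somata
run away); an iteration in which fewer than half the rays find a boundary
aborts as non-converged (open structure or image edge); centroid and
plane iterations are capped at 20 and 10. The boundary is located at step
resolution only — we do not sub-sample the intensity profile — so radius
estimates carry an error up to about one step, which the acceptance
tolerance of `max(0.5 voxel, 10%)` reflects.

## Marching, termination, and post-processing

`trace_neuron()` drives the queue. A popped prediction is refined; the
branch terminates when refinement fails to converge, the radius falls
below `min_radius` (default 0.5 voxel — finer structures are about one
voxel wide and their exact morphology is not reliably recoverable), the
position leaves the volume, or the position lands within the radius of an
already-emitted node. The last rule is a loop guard for ring-like
artifacts and crossing neurites; it deliberately exempts the immediate
family (parent, grandparent, and siblings — children of the same parent),
because right after a bifurcation the two daughters are legitimately
within one radius of each other and must both survive. Seeds are treated
specially: the initial radius comes from a full-sphere burst (minimum
boundary-terminated ray length, matching the definition of radius), the
initial direction from the largest cluster over two opposite hemispheres,
and after refinement both `v` and `-v` hemispheres spawn children, so a
seed placed mid-neurite traces in both directions. The order — refine the
seed first, then sample both hemispheres — follows the narrative order of
the procedure; the alternative (sample first) differs only in the seed
node's own coordinates.

Marching from several seeds, or through crossover regions, produces
redundant paths. `merge_redundant_paths()` merges node pairs that lie
within the larger of their two radii and point within `pi/4` of each
other (the angle gate operationalizes "similar direction"; "within either
radius" is the literal distance rule), replacing each pair by its midpoint
with the mean radius, until no pair qualifies — which also makes the
operation idempotent. `prune_short_branches()` removes terminal branches
(last bifurcation to tip) shorter than an absolute length (default 5
voxels) or than a multiple of the bifurcation radius (default 2); the
defaults are this package's own, since only the two criteria, not values,
are prescribed, and both are exposed. An unbranched root-to-tip path is
never a pruning candidate.

Node matching for evaluation (`compare_to_reference()`) is a simplified,
greedy mutual-proximity matcher within twice the local reference radius
(floor 2 voxels): recall `(G-M)/G`, precision `(T-E)/T`, the length
proportion over matched test segments, and the proportion of reference
bifurcations with a matched test bifurcation. It is *not* the full
topology-aware DIADEM metric program, and scores should not be conflated
with DIADEM scores.

## What the phantoms emulate — and what they do not

`phantom_tree()` grows a seeded random binary tree of tapering capsules
(default 101-cubed grid, trunk radius 3–6 voxels, child radius 0.8 of the
parent, branch angles 25–40 degrees) and rasterizes it exactly: a voxel is
foreground iff its center lies within the local radius of a segment axis.
Ground truth (centerline polylines, SWC, total length, bifurcation count)
is recorded by construction, and `add_noise()` adds clipped additive
Gaussian noise on the 8-bit scale (SD 5–30 in the robustness series).
This emulates the synthetic vascular-tree class of validation data:
binary tubular trees with known truth, degraded by noise.

What it does not emulate: uneven staining and labeling, beaded neurites,
point-spread-function blur, intensity falloff with depth, or touching
structures from *other* trees. Passing the phantom suite therefore
demonstrates geometric correctness of sampling, refinement, branching and
book-keeping — not performance on difficult real stacks, where
pre-processing quality dominates (and where beaded or one-voxel-wide
neurites are explicit limitations of the approach).

## Problem sizes and reproducibility

The regression suite traces five seeded phantoms (depths 3–4, trunk radii
3–6, 101-cubed) from a single root seed each; the sampling-distance sweep
covers 1.5–4.5 in steps of 0.5 on one phantom; the noise series covers SD
5–30 in steps of 5. These sizes keep a full validation run in the
low minutes on one CPU while still exercising every branch level. The
pipeline contains no randomness — identical volume, seeds and
configuration give bit-identical SWC output — and all phantom generation
and noise are seeded, so every number in the test suite and in
`scripts/acceptance.R` is exactly reproducible.

```{r example, eval = FALSE}
ph <- phantom_tree(depth = 3, trunk_radius = 4, seed = 1)
tree <- reconstruct(ph$volume, ph$truth$root)
glance(tree)
compare_to_reference(tree, ph$truth$swc)
autoplot(tree, plane = "xz")
```

## Known limitations

* Branch detection near a junction depends on node placement: when a node
  approaches a bifurcation at an unlucky spacing, the two daughter
  clusters can appear merged on the sampling grid and one subtree is
  missed. The published remedy is interactive: add a seed on the missed
  branch. Proportions on the automatic single-seed suite reflect this.
* The matcher is intentionally simple; topology errors that the DIADEM
  metric would penalize (e.g. a correct node attached to the wrong
  parent path) can score well here.
* Radius estimates are step-resolution; sub-voxel radii require a smaller
  `step`, at proportional cost.
* Beaded neurites and structures about one voxel wide are out of the
  method's reliable regime.
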