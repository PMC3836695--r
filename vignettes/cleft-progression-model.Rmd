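---
title: "A Cellular Potts model of salivary gland cleft progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Cellular Potts model of salivary gland cleft progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftsim)
```

## The biological question

During branching morphogenesis of the embryonic submandibular salivary
gland, clefts — inward indentations of the epithelial bud surface —
subdivide the primary bud into daughter buds. Cleft *progression* (as
opposed to initiation) is known to involve epithelial proliferation,
actomyosin contractility, loss of cell–cell adhesion in the cleft region
and gain of cell–matrix adhesion there, but these factors cannot be
manipulated independently in organ explants. `cleftsim` implements a
two-dimensional Glazier–Graner–Hogeweg (GGH, Cellular Potts) model in
which each factor maps to one model parameter, so their separate and
joint contributions to cleft progression can be quantified in
simulation.

## The model

Each cell is a set of lattice sites carrying an identifier σ and a type τ
out of {OCC, IPC, CLEFT, MITOTIC, MATRIX}: outer columnar cells lining
the epithelium–matrix interface, inner polymorphic cells, the
pre-specified cleft-wall cells, cells currently growing toward division,
and the single unconstrained "matrix" compartment standing in for
basement membrane plus mesenchyme. The Hamiltonian is the sum of four
terms:

* **Contact energy** `J(τ_a, τ_b)` per neighbouring site pair belonging to
  different cells — higher J means weaker adhesion;
* **Area constraint** `λ_area (a − A)²` per cell;
* **Perimeter constraint** `λ_perim (p − P)²` per cell, with the
  perimeter counted as unit edges between a cell's sites and sites it
  does not own;
* **Focal point plasticity (FPP)** `λ (l − L)²` per link between two
  cells' centroids, the model's stand-in for the actomyosin-driven
  fibronectin "wedge" that drives clefting.

Dynamics are modified Metropolis: one Monte-Carlo step (MCS) is N copy
attempts (N = lattice sites); a random site and a random first-order
neighbour are drawn, and the neighbour's owner is overwritten with
probability `min(1, exp(-ΔH/T))` at the fixed fluctuation temperature
T = 10. One MCS corresponds to 48 s, so the standard 1500-MCS run covers
the 20-hour ex-vivo culture window; 1 px corresponds to 1.06 µm (the
study uses the two units interchangeably, and this package reports
lattice measurements in pixels).

### Geometry

The single-cleft model is a *local patch*: a 14 × 9 grid of 6 × 6-pixel
cells spanning an 86 × 96 lattice, resting on the bottom frame with
matrix above. Boundary cells are OCC, interior cells IPC; two facing
columns of six cells each are typed CLEFT, and a 2-px-wide,
one-cell-side-deep matrix finger between the topmost pair forms the
initiated cleft (initiation is not modelled; only stabilization and
progression are). We found a free-floating island bud unsuitable for the
single-cleft study: overall interface tension rounds the island up and
squeezes the cleft shut, which is why the anchored patch is the default
(`glandConfig(anchor = "slab")`). The organ-level model *is* the island:
a 16 × 16-cell bud with three clefts at near-equal arc spacing
(`organConfig()`).

The two cleft walls carry distinct internal type codes. The swept
cell–cell contact energy CC acts only across the wall–wall interface —
the adhesion that is lost as the cleft opens — while cohesion within
each wall stays at the epithelial baseline of 5. With a single wall
type, CC = 10 also acts between vertical neighbours within a wall, and
each wall unzips internally and splays into the matrix, which no
biological cleft does.

### The clefting force

Lateral FPP links join opposing wall cells rank by rank; their target
lengths follow the empirical width–depth relation
`W(D) = 402/(D + 11) − 5` px, measured from segmented time-lapse images
of progressing clefts. Vertical links chain each wall, and lateral links
run along the OCC boundary (targets one cell side) with the cleft mouth
cells tethered into that chain so the cleft hangs from the bud surface.

Targets are updated every 10 MCS from the measured matrix-finger depth
D: rank k of n sits at depth `max((k−1)s, D − (n−k)s)` and its target
becomes W of that depth, *but* ranks the front has not yet reached (one
cell side of look-ahead) are held at cell contact. The separating force
mimics fibronectin assembled between wall cells that have already
parted; prying all ranks from MCS 0 applies spring deviations of ~25 px
(gradients of order 500 energy units per pixel at λ = 10) and tears the
walls out of the tissue. A consequence of this gating is that a rank's
target steps *up* once — from the closed width to the wedge profile —
when the front first reaches it; engaged ranks only tighten thereafter.

### Mitosis

Every 100 MCS, `round(MR · N_epith / 100)` epithelial cells (split
between OCC and IPC by the configured fraction; round-half-up, with a
Bernoulli mode available) are flagged MITOTIC and instructed to grow:
their target area is doubled plus a small slack (8 px², default). The
slack matters: a crowded cell equilibrates a few pixels below its
target, so a target of exactly 2A would leave growth perpetually just
short of the division threshold. Division still requires the cell to
actually reach twice its original size; under-grown cells are deferred
one cycle. The division axis is a random orientation through the
centroid; daughters are re-typed by location (OCC if touching matrix,
IPC otherwise) and the boundary-touching daughter inherits lateral OCC
links. Cleft-wall cells are excluded from the mitotic pool so the FPP
pairing stays well-defined (configurable).

## Morphometrics

The epithelium–matrix boundary is traced as an ordered contour
(`traceBoundary()`, via `EBImage`'s contour follower). The cleft centre
is the boundary point whose 8-distance neighbours along the trace
subtend the smallest angle (candidates must fall below 150°, so flat
boundaries report no cleft; on anchored geometries, points whose angle
window touches the frozen frame are excluded, since the patch's corners
against the frame are tissue edge, not interface). From the centre,
points are included side by side while the mean squared perpendicular
residual of a total-least-squares line stays below a threshold
(default 2 px²); the last index before the threshold is exceeded is the
extremum. Depth is the distance from the centre to the midpoint of the
extrema segment; the spanning angle is subtended at the centre by the
extrema; the tilt angle is the smaller of the complementary angles
between the extrema segment and the depth segment. Clefts shallower than
5 px or wider than 160° are discarded; tilt below 45° marks a failed
cleft (filters apply in that order).

Two properties of the extrema rule deserve note. First, the windowed
mean reacts sluggishly once a long straight wall has been included, so
on *noiseless* boundaries the stop index overshoots the mouth onto the
bud surface by a few points; `refineMouth = TRUE` moves the extremum to
the sharp bend near the window's end and recovers analytic fixtures to
within 1 px / 3°. On rough simulated boundaries the raw stop is the
calibrated behaviour (it reproduces the printed spanning angle) and is
the default. Second, the line-growth construction requires walls that
emanate from the centre: a parallel-walled channel with a semicircular
bottom cannot be traversed (the window stops inside the bottom curve),
which is why the fixture generator's "U" profile is a blunt-tipped
flaring channel.

The same functions accept integer label masks (0 = matrix), so the
morphometrics can be applied to segmented microscopy unchanged.

## What the synthetic generator emulates — and what it does not

`syntheticCleftMask()` rasterizes slabs with V- or blunt-tipped
U-shaped clefts of known depth, mouth width and tilt, with optional
uniform wall jitter, and rounds the slab's own corners (a square convex
corner subtends a sharper 8-distance angle than a gentle cleft bottom, a
shape no tissue boundary exhibits). Passing the fixture checks shows the
geometric indices are computed correctly; it does not validate the
biology of simulated boundaries, whose roughness, bulges and moving
surface have no analytic ground truth.

## Calibration of unstated constants

The published model fixes T = 10, the cell and cleft geometry, the base
parameter set (mitosis rate 1% per 100 MCS split evenly, cleft FPP
λ = 10, cleft CC = 10 with baseline 5, cleft CM = 3) and the width–depth
rule, but not the lattice dimensions, neighbourhood orders, constraint
strengths or the baseline epithelium/matrix contact energies. Those were
calibrated once against the base case and then frozen:

| constant | value | note |
|---|---|---|
| lattice (single cleft) | 86 × 96 slab | fits the 36-px cleft with 3 IPC rows beneath |
| lattice (organ) | 140 × 140 island | three clefts at arc spacing 21⅓ cell sides |
| contact neighbourhood order | 4 (20 neighbours) | copy attempts stay first-order |
| λ_area / λ_perim | 2 / 2 | |
| target perimeters (OCC/IPC/cleft) | 24 / 28 / 28 | square baseline, marginal IPC increase |
| baseline J (OCC–OCC, IPC–IPC, OCC–IPC) | 4 / 6 / 5 | keeps the published ordering around 5 |
| J (OCC–matrix, IPC–matrix) | 8 / 20 | high IPC–matrix penalty preserves the layering |
| vertical cleft-link target | 7.2 px | keeps the wall stack extended under compression |
| mitotic growth slack | 8 px² | crowding offset, see above |
| W(D) floor | 2 px | avoids degenerate targets |

The contact order is the decisive one: at order 2 the adhesion
energetics are small against T = 10 and the cleft channel neither opens
nor stays matrix-filled.

## Numerical choices and degenerate inputs

Ties at ΔH = 0 are accepted (e⁰ = 1). A copy attempt that would
annihilate a non-matrix cell is rejected, so the cell count only changes
through division. No connectivity constraint is enforced;
`fragmentCounts()` monitors multi-component cells so the T = 10 regime
can be verified (base-case runs keep almost all cells in one piece). The
lattice border is a frozen one-site frame that is never overwritten. All
randomness — copy attempts, mitotic selection, division axes — flows
through a single splitmix64 generator owned by the simulation, so a run
is bit-reproducible from (configuration, seed); replicate seeds are a
pure function of the master seed and replicate index. A rare replicate
can shed a small epithelial fragment, which the strict single-component
tracer rejects; replicated drivers drop such replicates rather than
guessing which component to measure.

## Problem sizes

The packaged defaults are desk-scale: replicated conditions use 20
replicates of 1500 MCS (the study ran 70–100), and the
feature-importance smoke analysis uses a reduced 2 × 3 × 2 × 2 grid with
3 replicates per combination rather than the full 600-combination,
40-replicate sweep, which `runSweep(sweepGrid())` will happily run as a
batch job (roughly a day of compute on one core). The two-cell
calibration experiment (`twoCellCalibration()`) reproduces the reduced
simulation used to choose workable λ ranges; its separation frontier is
fitted with a linear surface since the published fit's functional form
is shown only graphically, and no coefficients are asserted.

## Known limitations

With the frozen calibration the model reproduces the base case
approximately (replicate-mean depth around 27–29 px against the printed
34.1; spanning within ~10–15% of 46°), the biphasic contractility
ordering (no links < λ = 1 ≤ λ = 30 < base, with the last two
separated by roughly one replicate standard error) and the shallower
three-cleft organ model. Its depth response to the
adhesion drive CC − 2·CM is, however, threshold-like around the base
point rather than the study's near-linear ~1.1 px per unit: the extreme
adhesion conditions (CC = 20 printed at 40.7, CC = 1 at 19.2, CM = 5 at
27.3) and the no-FPP noise floor (12.6) are reproduced directionally but
not at their printed magnitudes. Two structural reasons: depths beyond
the designed 36-px wedge would require the channel to advance past the
last linked rank into territory whose IPC–matrix contact penalty is
prohibitive, and with no or weak FPP the contact-driven unzipping floor
(~20 px at order 4) exceeds the printed no-FPP depth. For the same
reason the cell–matrix energy is *not* the least informative feature of
a reduced sweep in this implementation, unlike in the published
classifier ranking. Growth-factor kinetics, basement-membrane structure,
apoptosis, mesenchymal cell agents and 3D lattices are out of scope, as
in the source model.
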