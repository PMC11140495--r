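---
title: "Tracing flexible particle lattices in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing flexible particle lattices in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticepick)
```

## The problem

Many complexes studied by cryo-electron tomography (cryoET) do not float
freely: they assemble into locally ordered arrays — retroviral Gag shells on
spherical membranes, bacterial surface layers, nuclear egress complexes on
membranes, axonemal repeats along microtubule doublets. Subtomogram
averaging needs the position and orientation of every copy, and on such
lattices the copies are not independent: each particle predicts where its
neighbors sit and roughly how they are oriented.

`latticepick` exploits that prior. Starting from a handful of manually
picked seed particles it traces the lattice outward: each iteration
predicts candidate positions next to the current seeds through a
user-defined *transition list* (local-frame displacement vectors
`[sx, sy, sz]` to the expected neighbors), aligns a subvolume at each
candidate against a reference by masked normalized cross-correlation over a
restricted pose grid, accepts candidates whose correlation clears a
threshold, and promotes them to seeds for the next iteration. The run stops
when no candidates remain or an iteration cap is reached. The result is a
particle table in the Relion-4 tomogram STAR convention.

Around that core the package provides geometry-based particle cleaning
(neighbor counts and averaged inter-axis tilt), the deterministic halves of
segmentation-based picking (cube-label volumes for training targets,
cluster-centroid coordinate retrieval from segmentation maps), place-back
export, and a synthetic-data module that renders ground-truth lattices so
every stage is testable without external data.

## Conventions

* **Coordinates** are 0-based continuous voxel indices with the origin at
  the volume corner; volumes are indexed `[x, y, z]` with x fastest,
  matching the MRC layout.
* **Orientations** are intrinsic ZYZ Euler angles `(rot, tilt, psi)` in
  degrees; the matrix `Rz(rot) Ry(tilt) Rz(psi)` maps particle-local
  coordinates into tomogram coordinates. This is the Relion convention the
  STAR export targets.
* **The particle axis is local Y** (the stalkInit two-point convention: a
  pair of points defines the axis, the center is their midpoint).
  `yaxis_to_z()` converts to the Relion Z-axis convention; the two-point
  pick leaves the in-plane spin unresolved, so seeds carry the minimal
  rotation from +Y to their axis and the restricted angular search absorbs
  the rest.

## The search grid and its offset parametrization

The alignment enumerates rotation offsets from half-ranges and steps and
composes them intrinsically after the prior orientation. Small ZYZ Euler
offsets would be the obvious parametrization, but they degenerate: to first
order `Rz(a) Ry(b) Rz(c)` has rotation vector `(0, b, a + c)` — no
component about local X at all, so a prior-to-truth rotation about local X
(exactly what stepping sideways on a curved lattice produces) would be
unreachable at any range. Offsets are therefore enumerated as intrinsic
Z-Y-X rotations: `rot` about local Z, `tilt` about local Y (the particle
axis, i.e. the in-plane spin) and `psi` about local X, which spans all
three rotational degrees of freedom at first order. Storage and I/O remain
ZYZ.

On spherical lattices the spin range deserves a wide setting (see below);
the two tilt-like ranges need only cover the geodesic step
(`spacing / radius`, about 11.5 degrees for the bundled sphere fixture)
plus lattice distortion.

## Correlation, interpolation symmetry, and the sub-grid polish

`masked_cc()` is a mask-weighted Pearson correlation: both volumes are
mean-centered and variance-normalized under the mask weights, and a masked
variance below `1e-12` yields 0 rather than noise. The mask is applied in
the extraction frame and is not rotated with the reference; use a spherical
mask unless you know better.

Two numerical choices matter more than they look:

* **Interpolation symmetry.** The subvolume is taken at raw grid voxels
  (integer window, no interpolation); the fractional part of the candidate
  center and the full rotation are folded into the *reference* sampling
  coordinates (one trilinear pass). A synthetic volume rendered by one
  interpolation pass is then compared against a reference sampled by one
  interpolation pass: at the true pose both sides sample identical
  arguments, so the correlation optimum sits exactly on the true pose
  instead of being displaced by asymmetric smoothing. Shifts are
  consequently integer-valued at the grid stage.
* **The position–orientation ridge.** An integer shift grid aliases
  sub-voxel lattice positions into compensating orientation error: a
  residual lateral offset of half a voxel is mimicked by a rotation of
  roughly `0.5 / r` radians for features at radius `r` (about 10 degrees
  here). The discrete argmax can therefore sit a cell or two *along the
  ridge*, and can even rank a secondary basin above the true one. When
  `refine_subgrid` is enabled (the default), the best few
  mutually-separated rotation candidates, the prior pose, and the running
  optimum are each polished by a bounded continuous optimization:
  exhaustive 1-degree scans about each local axis with the position held
  fixed (immune to the ridge), alternating with a bounded Nelder–Mead
  position refit, and a final joint sub-degree refinement. Only strict
  correlation improvements are accepted, so the returned score never drops
  below the grid argmax, and with all ranges zero the prior pose is
  returned unchanged. The polished score is a local *maximum* of the
  correlation in a neighborhood of the searched region; for empty candidate
  positions near real density it can sit noticeably above the raw grid
  score while remaining far below the acceptance threshold.

## Expansion bookkeeping

A position is *picked* once it is a seed or accepted; picked positions are
never proposed again. Candidates within `d_min` of a picked particle or of
an earlier candidate in the same iteration are dropped (first occurrence
kept; enumeration order is seed order, then transition order). Rejected
positions may be re-proposed from a different seed in a later iteration — a
different prior orientation can align better on curved lattices — capped at
`max_attempts` alignment attempts per spatial cell of side `d_min` so the
run always terminates. Accepted particles seed the next iteration with
their *refined* poses. Because refinement can move a candidate, accepted
particles are merged into the final set with an explicit `d_min` duplicate
check, earlier particles taking precedence. `d_min` defaults to half the
lattice constant: half the spacing separates distinct sites under any
deformation the restricted search can follow.

Each iteration is persisted as one JSON record in a `<tomo>_cache`
directory (seeds in, all aligned candidates with prior and refined poses
and scores, the threshold and `d_min`), next to a `<tomo>` working
directory with the run log and a `<tomo>_final` directory with the final
STAR — the three-directory layout per tomogram. `regather()` re-applies a
(possibly different) threshold to the cached scores and rebuilds the final
set without any new alignment; out-of-volume candidates are recorded with
`cc = NA` and always count as rejected.

## The synthetic world

The generators state the world the tests live in; a green test establishes
correctness *in that world* and nothing more.

* **Template.** Four Gaussian blobs of distinct width and amplitude: a
  center blob, one along +Y marking the axis, and two off-axis blobs that
  put roughly half the energy into in-plane features so the spin is
  sharply recoverable. Two blobs (the minimal asymmetric layout) would
  leave a continuous spin degeneracy about the axis through their centers;
  near-equal widths would let a flipped-and-shifted copy impersonate the
  original at high correlation (a failure mode the test suite exercised
  into existence). Every blob is smoothly truncated so the whole template
  vanishes beyond `reach` (default 4 voxels, half the lattice constant):
  neighboring copies on the lattice then contribute exactly zero inside an
  alignment mask of the same support, which keeps the correlation optimum
  free of neighbor-density bias — without truncation the neighbor tails
  inside the mask genuinely move the optimum by several degrees.
* **Rendering** sums one rotated, shifted template copy per site
  (trilinear) plus i.i.d. Gaussian noise; a fixed RNG seed makes the volume
  bit-reproducible, and the caller's RNG state is restored. No missing
  wedge and no CTF: the tracer operates on reconstructed tomograms as
  given, and those effects are out of scope.
* **The worked two-patch fixture** is constructed so the iteration-0
  bookkeeping holds analytically: a radius-4 hexagonal patch (61 sites)
  minus one interior site leaves 60; three seeds at axial `(4,0)`, `(0,0)`,
  `(-3,0)` propose `3 x 6 = 18` distinct candidates of which exactly 14
  coincide with density-bearing sites (the other four: three outside the
  patch edge, one at the removed site). A disjoint 7-site patch at least
  four lattice constants away stays untouched by iteration 0. Later
  iterations depend on unpublished figure geometry and are deliberately not
  reproduced.
* **The spherical lattice** is a Fibonacci point set relaxed under a band
  constraint (pairs pushed apart below `0.992 d`, each site pulled toward
  its nearest neighbor above `1.008 d`) so every nearest-neighbor distance
  lands within 1% of the lattice constant. The site count is set to 93% of
  the flat-packing estimate `4 pi R^2 / (sqrt(3)/2 d^2)`: at full density
  the twelve disclinations any spherical hexagonal packing must carry make
  the 1% band unattainable (the relaxation jams); 7% of dilution is the
  price of metric uniformity on a curved surface. With partial `coverage` a
  contiguous cap is retained; rim sites may lose their nearest neighbor to
  the cut, so the spacing band is a full-sphere property.
* **Sphere frames.** Local Y is radial. Any tangent frame field on a
  sphere carries two vortices (hairy-ball theorem); the spin reference
  follows the azimuthal direction around an axis chosen through lattice
  *face centers*, so both vortices sit maximally far from sites. Each spin
  is then snapped to the local lattice azimuth modulo the 60-degree
  hexagonal symmetry (circular mean), which points the transition fans at
  actual neighbors. The residual inter-site spin mismatch is the smooth
  lattice-orientation gradient plus exact 60-degree jumps along the fold
  seams radiating from the vortices — hence the recommended wide spin
  search range (±60 degrees or more) on spherical lattices, and hence the
  one-or-two sites adjacent to a vortex whose priors no affordable range
  can reach. The single-seed recovery test seeds at the vortex equator,
  where the twist is minimal.
* **Filaments** repeat along a circular arc (curvature 0 gives a line)
  with exact arc-length spacing, local Y the outward normal and local X the
  tangent.

## Defaults and degenerate inputs

* `cc_threshold` defaults to 0.5, appropriate for noise-free fixtures
  (on-site scores approach 1.0, off-site scores stay near 0); real data
  needs an explicit choice. At a template peak-to-noise ratio of 3 the
  on-site scores drop to about 0.55–0.65, so 0.5 is then a *tight*
  threshold and recovery of weak sites, not false positives, is the
  limiting factor.
* Cleaning: `radius = 1.5 x spacing`, `min_neighbors = 3`,
  `max_tilt = 30` degrees. The tilt is the angle between lattice-normal
  axes (particle vs neighbor), not to the displacement vector: that makes
  the flat-plane value exactly 0 and the sphere value `degrees(d / R)`,
  the curvature semantics wanted for coloring. Axes are directed by
  default (angles in `[0, 180]`, so inside-out flips are caught);
  `fold_axes = TRUE` folds to `[0, 90]`. Particles with no neighbors have
  undefined tilt and can only fail the count rule.
* Segmentation: cube side defaults near a quarter of the spacing (odd,
  at least 3) so labels never bridge adjacent sites; probability maps are
  binarized at 0.5; single-linkage clustering with a cutoff of a few voxels
  and a minimum cluster size reject speckle. For large maps clustering runs
  per 26-connected component, which is provably identical to global single
  linkage whenever the cutoff is at least `sqrt(3)` (adjacent voxels are
  then always linked); below that the global algorithm is used.
* Ties in the grid search break toward the smallest shift norm, then the
  smallest angular offset norm, then enumeration order, making runs
  bit-reproducible.

## What the tests establish — and what they cannot

The acceptance suite reproduces the worked example's iteration-0 counts
(3 seeds, 18 candidates, 14 accepted) exactly, recovers at least 99% of a
noise-free full-coverage spherical lattice (one seed, six-transition list,
4-degree step) within half a lattice constant and one angular step about
each axis, and at least 90% with no more than 2% false positives at a
peak-to-sigma ratio of 3. Published dataset-scale numbers (tens of
thousands of particles, subnanometer resolutions) are *not* reproducible
here: they require the original tilt series, manual seeding and external
high-resolution refinement. The synthetic world also omits the missing
wedge, CTF modulation and structured background, so detection thresholds
tuned here do not transfer to real tomograms unchanged.

## Known limitations

* The exhaustive pose grid is the reference implementation; it is
  desk-scale (seconds per candidate), not production-scale.
* One or two sites adjacent to a frame-field vortex on a full sphere can
  be first-proposed with an unreachable spin prior and end up missing or
  misoriented; re-proposal heals most but not provably all of them.
* IMOD binary model files are not parsed; seed pairs travel as plain text
  (`x1 y1 z1 x2 y2 z2` per line).
* Place-back emits a documented plain-text transform table (plus optional
  ChimeraX `.cmm` markers), not an application session file.
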