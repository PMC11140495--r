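# latticepick

Lattice-aware particle picking for cryo-electron tomography, in R.

Repeating complexes in cryoET tomograms — retroviral Gag shells, bacterial
S-layers, membrane-bound nuclear egress complexes, axonemal repeats — sit on
flexible, imperfect 1D–3D lattices. `latticepick` turns a handful of
manually picked *seed* particles into the full particle set by iterative
lattice tracing ("auto expansion"):

1. **Propose.** For every seed `s` and every transition `t = [sx, sy, sz]`
   in a user-defined transition list (local-frame displacements to the
   expected neighbors), propose a candidate at
   `position(s) + R(s) · t`, carrying the seed's orientation as the prior.
   Already-picked positions are never re-proposed.
2. **Align.** Extract a subvolume at each candidate and align it to a
   reference by masked normalized cross-correlation
   `cc = Σ w (a − ā)(b − b̄) / √(Σ w (a − ā)² Σ w (b − b̄)²)`
   over an exhaustive grid of restricted rotations (intrinsic offsets about
   the local Z, Y, X axes) and integer shifts, followed by a bounded
   sub-grid polish.
3. **Accept.** Candidates with `cc ≥ cc_threshold` join the particle set
   with their refined poses and seed the next iteration; the run stops when
   no candidates remain or at the iteration cap.

Orientations are intrinsic ZYZ Euler angles (Relion convention); particle
axes follow the stalkInit local-Y convention, with `yaxis_to_z()` for the
Relion Z-axis. Output is a Relion-4 tomogram-convention STAR table.

The package also provides geometry-based cleaning (neighbor count and mean
inter-axis tilt as a curvature proxy), training-label generation and
clustering-based coordinate retrieval for segmentation-based picking,
threshold "regathering" from the per-iteration cache without re-alignment,
place-back export, and a synthetic-data module (hexagonal lattices on
planes and spheres, filament repeats, oriented-template rendering with
Gaussian noise) that makes the whole pipeline testable offline.

## Worked example

The bundled two-patch hexagonal fixture reproduces the tracer's worked
bookkeeping: two patches of 60 and 7 sites (lattice constant 8 voxels),
three seeds, a six-neighbor transition list, and a noise-free rendering of
an asymmetric four-blob template at every site.

```r
library(latticepick)

fx <- make_fig3_fixture(spacing = 8)
run <- run_expansion(fx$volume, fx$seeds, fx$reference, fx$mask,
                     fx$params, verbose = TRUE)
#> iteration 0: seeds=3 candidates=18 accepted=14 rejected=4
#> iteration 1: seeds=14 candidates=26 accepted=18 rejected=8
#> iteration 2: seeds=18 candidates=21 accepted=14 rejected=7
#> iteration 3: seeds=14 candidates=20 accepted=11 rejected=9
#> iteration 4: seeds=11 candidates=17 accepted=0 rejected=17
#> stop: no_candidates; final particles: 60
```

Iteration 0 is the designed worked example: the 3 seeds propose 18 distinct
candidates, of which 14 sit on density-bearing lattice sites and clear the
correlation threshold (the other four: three beyond the patch edge, one at
a deliberately removed site; their scores stay near 0 against ~1.0 for true
sites). The trace then floods the rest of the 60-site patch in four more
iterations and stops when every proposal is either already picked or lands
on empty density. The disjoint 7-site patch is never reached — it needs its
own seed, which is why seeds are placed on every observed patch.

Downstream:

```r
stats <- neighbor_stats(run$final, radius = 12)   # counts + mean tilt
bad   <- classify_bad(stats, min_neighbors = 3, max_tilt = 30)
export_placeback(run$final, stats, "fig3", bad = bad)  # markers + clean STAR
write_star_particles(run$final, "fig3_particles.star")
```

A command-line front end wraps the same stages
(`latticepick simulate | seeds | expand | regather | clean | labels |
seg2coords | placeback | assemble`, see `exec/latticepick --help`).

## What this is not

No tilt-series processing, reconstruction or CTF estimation; no neural
network (only its training targets and the consumption of its maps); no
GUI; no missing-wedge or CTF simulation; desk-scale exhaustive search, not
a production GPU pipeline. See the vignette
(`vignettes/lattice-tracing.Rmd`) for the model, the synthetic world and
its limits.
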