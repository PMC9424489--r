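---
title: "Quantifying 3D lymphatic vessel networks: models, parameters and design choices"
author: "LymphNetQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D lymphatic vessel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LymphNetQuant)
```

## The problem

Hepatic lymphatic vessels form a distinctive network confined to the portal
tracts: long vessels run parallel to the portal vein while dense,
blind-ending capillary initials clasp it perpendicularly like the rungs of a
ladder. Under reduced VEGF-C signalling this network rarefies — initials
thin out, ramify less, and longitudinal vessels can become discontinuous —
and the quantitative signature of that phenotype is a shift of the segment
census: the surviving inter-branchpoint segments are *longer* and have a
*larger average cross-section area*, because the census loses its thin,
short, densely branching members.

`LymphNetQuant` turns a single-channel 3D fluorescence volume of such a
network into a refined spatial graph with per-segment morphometrics, and
compares two groups of networks with a nonparametric test. Because suitable
public volumes are scarce, the package ships a synthetic phantom generator
with exact ground truth, so every stage — and the group comparison itself —
is testable end to end.

## Pipeline model

The quantification follows a fixed stage order:

1. **Tissue ROI (optional).** A crude intensity threshold separates tissue
   from the empty bath; each z-slice's foreground is replaced by its filled
   concave hull; the stacked hull is eroded by a physical depth. Analysis is
   then restricted to the eroded interior.
2. **Hysteresis thresholding.** A voxel is kept iff its intensity is at or
   above the *lower* limit and it is connected (26-connectivity by default)
   through such voxels to at least one voxel at or above the *upper* limit.
   Both limits are inclusive. This keeps dim vessel stretches only when they
   are anchored to a bright core.
3. **Component curation.** Connected components are labelled
   deterministically (numbered by the lexicographically smallest member
   voxel in (z, y, x) order); components below a voxel-count threshold are
   discarded; an explicit label list reproduces expert removal of
   incorrectly segmented structures, with `componentTable()` providing the
   audit table (size and physical centroid per component) from which a
   curator picks labels.
4. **Skeletonization.** Homotopic 3D thinning removes simple border points
   in six directional subiterations, deleting sequentially with re-testing,
   which preserves the topology of the mask exactly and keeps curve
   endpoints. Anisotropy is handled by measuring in physical units, never by
   resampling.
5. **Graph building.** Skeleton voxels are classified by their 26-neighbour
   count (1 endpoint, 2 chain, 3+ branch voxel); adjacent branch voxels
   collapse into one branchpoint at their radius-weighted centroid; chains
   become edge polylines in micrometres with per-point radii from the
   spacing-aware Euclidean distance transform of the curated mask.
6. **Iterative refinement.** Until a fixpoint: terminal twigs shorter than
   `spurLength` are pruned (unless they are their component's last edge);
   branchpoints joined by an edge shorter than `nodeMergeRadius` merge at
   their radius-weighted midpoint; chains through degree-2 nodes fuse.
   Refinement never increases the edge count and running it twice equals
   running it once.
7. **Morphometry.** One record per edge: arc length (sum of Euclidean
   distances between consecutive polyline points) and average cross-section
   area, the mean of pi r^2 over the polyline's *interior* points —
   endpoints are excluded whenever more than two points exist, because
   distance-transform radii at junctions reflect the junction blob, not the
   vessel.
8. **Group comparison.** A self-contained two-sided Mann-Whitney U test:
   exact by full enumeration when the pooled sample has at most 12
   observations and no ties, otherwise a normal approximation with
   continuity correction and tie-corrected variance. Significance is
   declared at p < 0.05 per feature, with no multiple-testing correction
   across the two features.

## Key parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| lateral/axial spacing | 2 | um | explicit geometry; the stepping axis is z |
| hull `alpha` | 100 | um | bridges concavities up to portal-tract scale |
| `erosionRadius` | 50 | um | removes the cut/cleared tissue surface |
| hysteresis `low`/`high` | mean + 2 SD / mean + 4 SD | counts | per-volume automatic rule used for synthetic runs; real volumes take manual per-volume limits |
| `minSize` | 500 | voxels | rejects specks while keeping any true vessel branch |
| connectivity | 26 | – | keeps diagonal runs of thin bright tubes connected |
| `spurLength` | 10 | um | prunes thinning artefacts (a few voxels) but not true initials (tens of um) |
| `nodeMergeRadius` | 5 | um | one anatomical junction spans a few voxels of branch blob |
| `maxIterations` | 10 | – | safety cap; fixpoint is normally reached in 2-3 sweeps |
| unit of analysis | segment pooling | – | volume-mean comparison also implemented; pooling is the default because the phenotype lives in the segment census |

## The phantom generator

`phantomSpec()` declares the study conditions. The default control phantom
is a 301 x 256 x 256 voxel grid at 2 um isotropic spacing whose z extent of
600 um between first and last voxel centres carries the portal-tract axis
exactly: a gently curved axis (sinusoidal amplitude 8 um), two longitudinal
vessels of radius 6 um at 30 um offset (portal tracts are tens to hundreds
of micrometres across), blind-ending initials of radius 3 um and length
40 +/- 10 um placed as opposite-side pairs at Poisson axial positions with
a mean inter-initial distance of 30 um, and short finger-like tips of
radius 2 um and length 18 +/- 4 um ramifying from the initials (two per
initial on average). Radii taper tip < initial < longitudinal, which is
what couples the census composition to the rarefaction phenotype.

The mutant emulation (`mutantSpec()`) scales *both* the initial rate and
the per-initial tip rate by `initialDensityFactor` (0.4 in the acceptance
runs) and breaks each longitudinal vessel with probability
`discontinuityProb` (0.1) by a 30 um gap. Removing rungs merges adjacent
longitudinal spans (longer segments) and shifts the census toward the
thick longitudinal calibre (larger average cross-section) — both effects
emerge from the geometry; nothing is imposed on the features directly.

Intensities are integer photon-like counts: tubes at 200 counts over a
background of 20, a light sub-voxel Gaussian blur (sigma 0.5 um) to
regularize tube edges, and additive Gaussian noise (sd 10, i.e. a
signal-to-noise ratio of 20, typical of a good light-sheet acquisition).
Realistic optics (stripe artefacts, depth attenuation, shot noise) are
deliberately out of scope: the phantom exercises the pipeline's geometry
and statistics, not image restoration.

Dimensioning choices were made once, a priori, for resolvability at the
declared 2 um spacing: the thinnest structure (tips) spans about two
voxels, tip lengths are truncated at 12 um so no true tip falls below the
10 um spur threshold, and tips attach on the proximal 15-60 % of their
stem so terminal stem stubs usually exceed the spur threshold as well. A
generator whose true anatomy sat below the pipeline's declared resolution
limits would conflate generator and pipeline error.

**What passing tests do and do not show.** Ground-truth recovery on
phantoms demonstrates the pipeline's geometric and topological
correctness under the stated intensity model. It does not validate
segmentation on real light-sheet data, where illumination artefacts,
antibody penetration gradients and sinusoidal background structures
dominate threshold choice — which is why hysteresis limits remain a
per-volume manual setting in real use.

## Numerical conventions

- **Axis order** is (z, y, x); all voxel scans are lexicographic in that
  order, making labelling, thinning and graph extraction bit-reproducible
  and translation invariant. Total network length under axis permutation
  (with matching spacing permutation) agrees to within a few percent; the
  directional subiteration order makes it not bit-identical.
- **Distances** are measured between voxel centres.
- **Radius convention.** A skeleton voxel's radius is the spacing-aware
  Euclidean distance to the nearest background voxel centre, with no
  half-voxel correction. On rendered digital cylinders this estimator
  recovers cross-section areas within roughly 10 % across the 2-8 um
  calibre range, whereas subtracting half a voxel biases areas low by
  nearly 20 % at 1 um sampling. The estimator carries a positive bias of
  up to one voxel step, which is why a single isolated voxel reports a
  radius of one voxel spacing rather than half.
- **Concave hull.** The slice-wise "concave hull" is the filled alpha-hull,
  computed as morphological closing with a disc of physical radius alpha
  followed by cavity filling. By the union-of-balls characterization, the
  complement of the alpha-hull is the union of radius-alpha discs avoiding
  the foreground — exactly the complement of the closing — so no Delaunay
  machinery is needed and the convex-hull limit holds as alpha grows.
- **Erosion** thresholds the distance transform, which is exactly Minkowski
  erosion by the digital ellipsoid (verified against brute force in the
  tests); the grid boundary counts as background.
- **Degenerate inputs.** Empty masks give empty skeletons and graphs;
  isolated single skeleton voxels are dropped during graph building (they
  cannot satisfy the degree invariants); pure chain cycles become a
  self-loop edge anchored at the lexicographically smallest voxel, whose
  anchor node may legitimately keep degree 2.
- **Exactness switch** for the U test at pooled n of 12 keeps full
  enumeration below 1000 assignments; beyond that the tie-corrected normal
  approximation differs from the exact value by well under 0.02 in the
  regimes the package reports.

## Design choices where the design was open

- The refinement rules and their thresholds are a declared reconstruction
  of "iterative refinement": three local rules run to a fixpoint, fully
  exposed in `refineParams()`. Branchpoint merging is triggered by the
  *arc length of the connecting edge* rather than raw coordinate distance,
  so spatially close but topologically distant nodes are never collapsed.
- Expert curation is reproduced as a config-level excluded-label list plus
  the exported per-component audit table, making the manual step auditable
  and replayable.
- The automatic hysteresis rule (mean + 2 SD / mean + 4 SD) is declared for
  synthetic experiments only; it is not a reproduction of any published
  per-volume limit.
- The ROI stage is optional in the pipeline configuration. Phantoms fill
  the grid with tissue-like background, so their quantification runs
  without ROI; the ROI operators are validated on their own fixtures.
- Volumes are exchanged as multi-page TIFF (8/16-bit integer exactly;
  32-bit float restricted to [0, 1]); graphs as JSON (lossless reference)
  plus GraphML for interoperability. Phantom intensities are integer
  counts so written volumes round-trip bit exactly.
- Cohort seeding: member k of a cohort uses `seed + k`; the acceptance
  script derives control seeds `base + 1..8` and mutant seeds
  `base + 101..108` from its single `--seed` (base = (seed-1)*1000), so
  the default run uses seeds 1-8 and 101-108.

## Problem sizes

The test suite and the acceptance script run the full pipeline on default
301 x 256 x 256 phantoms (8 control + 8 mutant for the group comparison;
4 control for ground-truth recovery), and use a reduced 120 x 110 x 110
geometry with proportionally shortened axis and initials for module-level
tests. Type-I error control is measured on 20 pairs of identically
generated cohorts using their exact ground-truth graphs, which isolates
the statistical behaviour from segmentation noise.

## Known limitations

- The radius estimator's voxel-scale positive bias inflates areas of
  near-voxel-calibre structures (tips); comparisons between groups share
  the bias, rank order across calibres is preserved, and the bias shrinks
  with finer sampling.
- Loops created by touching structures are kept as cycles; no
  Strahler-type ordering, flow modelling, or vessel-type classification is
  attempted.
- The hull is slice-wise 2D by construction, matching a stack-of-slices
  acquisition; a true 3D alpha-shape is out of scope.
- Mann-Whitney U on pooled segments treats segments as exchangeable across
  volumes within a group; the volume-mean unit is provided for analyses
  that must respect per-animal clustering.
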