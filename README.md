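# LymphNetQuant

Quantification of 3D lymphatic vessel networks from light-sheet style
fluorescence volumes, built for the hepatic lymphatic vasculature: long
lymph vessels run along the portal tracts while blind-ending capillary
initials clasp the portal vein perpendicularly like the rungs of a ladder.
Under reduced VEGF-C/VEGFR-3 signalling this network rarefies, and the
measurable signature is a census shift — significantly **longer segments
between branchpoints** with **higher average cross-section areas**. The
package provides the full path from raw volume to that statistical
comparison, for imaging scientists and vascular biologists who need a
reproducible, scriptable alternative to interactive tool chains.

## What it computes

From a volume `V` with voxel spacing `(dz, dy, dx)` in µm:

1. optional tissue ROI: slice-wise filled concave hull (alpha-hull, scale
   α) of the tissue mask, globally eroded by a physical depth;
2. hysteresis segmentation: voxel kept iff `V ≥ low` and connected through
   such voxels to some voxel with `V ≥ high` (26-connectivity);
3. component curation: deterministic labelling, size threshold, explicit
   excluded-label list with an exported audit table;
4. homotopic 3D thinning to a unit-width skeleton with radii `r(p)` from
   the spacing-aware Euclidean distance transform;
5. skeleton → spatial graph (endpoints, branchpoints, centreline
   polylines) with iterative refinement (spur pruning, junction merging,
   chain fusion) run to a fixpoint;
6. per-segment morphometry: arc length `L = Σ‖p_{i+1} − p_i‖` and average
   cross-section area `Ā = mean_i π r_i²` over interior polyline points;
7. two-group comparison with a self-implemented two-sided Mann-Whitney U
   test (exact by enumeration for pooled n ≤ 12 without ties, otherwise
   normal approximation with continuity and tie correction), significance
   at p < 0.05 per feature.

A synthetic phantom generator (`phantomSpec()`, `generatePhantom()`,
`generateCohort()`) renders ladder-like control networks and rarefied,
discontinuous mutant-like networks with exact ground-truth graphs, so the
whole pipeline is testable without any imaging data.

## Worked example

```r
library(LymphNetQuant)

ctrl <- phantomSpec(seed = 1L)              # 301 x 256 x 256 @ 2 um
ph   <- generatePhantom(ctrl)
q    <- quantifyVolume(ph$volume, segmentationParams(), volumeId = "demo")
q$graph
#> VesselGraph: 147 nodes (76 endpoints, 71 branchpoints), 173 edges,
#>   total length 3465.3 um
head(q$features, 3)
#>   volume_id edge_id length_um avg_cross_section_um2 n_points
#> 1      demo       1 16.149674              27.74025        8
#> 2      demo       2  8.972056              59.41877        5
#> 3      demo       3 22.127967              45.33667       11
```

`length_um` is the inter-branchpoint arc length of one vessel segment and
`avg_cross_section_um2` its mean π r² over interior centreline points; the
graph summary shows the network topology the refinement settled on.

Comparing a control and a rarefied cohort (this is the headline
computation, here at reduced size for illustration):

```r
mut <- mutantSpec(ctrl, densityFactor = 0.4, discontinuityProb = 0.1)
fc <- do.call(rbind, lapply(1:4, function(k) {
  s <- ctrl; s@seed <- k
  quantifyVolume(generatePhantom(s)$volume, segmentationParams(),
                 volumeId = paste0("c", k))$features
}))
fm <- do.call(rbind, lapply(101:104, function(k) {
  s <- mut; s@seed <- k
  quantifyVolume(generatePhantom(s)$volume, segmentationParams(),
                 volumeId = paste0("m", k))$features
}))
compareGroups(fc, fm, "length_um", labels = c("control", "mutant"))
#> Group comparison of length_um (segment unit)
#>   control: n = 561, median = 16.5
#>   mutant: n = 152, median = 21.5
#>   U = 33477, two-sided p = 1.163e-05 (normal_approx_tie_corrected)
#>     *significant at alpha = 0.05*
```

The mutant median segment is longer; the same call with
`"avg_cross_section_um2"` tests the second morphometric feature.

A file-based pipeline (`runSimulate()`, `runQuantify()`, `runCompare()`)
drives the same stages from a single YAML config with manifests for
reproducibility, and `inst/scripts/lymphnetquant.R` exposes it as
`simulate | quantify | compare | report` subcommands.

## Package layout

- `R/`, `src/` — S4 classes (`ImageVolume`, `VoxelMask`, `VesselGraph`,
  `PhantomSpec`, ...) and the Rcpp voxel core (hysteresis, components,
  distance transform, thinning, rendering);
- `vignettes/hepatic-lymphatic-morphometry.Rmd` — the methods vignette:
  model, parameters, numerical conventions, generator design, limitations;
- `tests/testthat/` — oracle-backed unit and property tests plus the
  end-to-end acceptance suite.
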