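---
title: "Detecting and measuring dendritic spines in 3D stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring dendritic spines in 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The problem

Dendritic spines are micron-scale protrusions on dendrites; each carries a
glutamatergic synapse, so spine density tracks connectivity and spine-head
size tracks synaptic strength. Spines sit at the edge of what confocal and
two-photon microscopy resolve: heads are a few hundred nanometres across,
necks thinner still, and the axial point-spread function (PSF) is three to
four times broader than the lateral one. `spinemorph` is a headless
pipeline that, given a 3D intensity stack and a reconstruction of the
dendrite in SWC format, detects spines, segments their heads, traces their
necks, and reports morphometrics — with every manual correction expressed
as a replayable, coordinate-based edit script rather than mouse clicks.

## The procedure

The pipeline runs in five stages.

**1. Dendrite realization.** An SWC reconstruction is a chain of nodes
`(x, y, z, radius)`. We rasterize it as the union of a sphere at every
node and a conical frustum along every parent–child segment, with the
radius linearly interpolated by projected arclength and the projection
clamped to the segment (which yields spherical caps at the nodes — the
natural reading of joining spheres by frustums, and the variant we keep
after checking that cap terms change capsule volumes by far less than the
rasterization tolerance). The set of inside voxels with a 6-connected
outside neighbour forms the dendrite *border*; an anisotropic Euclidean
distance transform (separable lower-envelope algorithm, implemented in
C++) gives every voxel its physical distance to that border.

**2. Seed detection.** Candidate spine heads are regional maxima of the
26-neighbourhood, restricted to a user-set *distance band*
`[dist_min, dist_max]` around the dendrite border and an intensity floor
`intensity_min`. The band is what rejects bright spines belonging to a
neighbouring dendrite; the floor rejects background. Iso-intensity
plateaus contribute a single seed, the lexicographically smallest voxel,
so ties are deterministic. Surviving maxima are sorted brightest-first
and thinned greedily so that no two seeds are closer than
`min_separation`. Manual seeds snap to the brightest voxel of the
in-plane 5×5 window around the given position and are exempt from all
three criteria.

**3. Head segmentation.** Each seed grows into a 3D object from the
intensity distribution around its maximum. The per-seed threshold is

> T = bg + f · (I_seed − bg)

where `bg` is a low quantile (default the 5th percentile) of intensities
on a thin shell of radius `radius_max` around the seed, and
`f = threshold_fraction` (default 0.5, the local half-maximum — the usual
operating point for diffraction-limited blobs). The head is the connected
component of `{I ≥ T}` containing the seed, clipped to `radius_max`
(default 1.5 µm) and to voxels outside the dendrite. Voxels claimable by
two heads go to the nearer seed, so a double-maximum head splits into two
adjacent, disjoint objects that `merge_heads()` can reunite. Two further
numerical choices matter in degenerate cases: voxels at or below `bg`
never join (otherwise a click on a perfectly flat background floods its
whole iso-intensity plateau; an epsilon of 10⁻⁹ relative absorbs float
jitter on constant regions), and a manual seed whose contrast over `bg`
is below 2 % of the image dynamic range is flagged `low_intensity` in the
output log.

**4. Neck tracing.** A spine is *stubby* when its head touches the
dendrite (26-adjacency by default; a stricter face-adjacency option
exists); stubby spines get neck length 0. Otherwise the closest pair of
border voxels (head border × dendrite border, anisotropic distance, ties
lexicographic) anchors a minimum-cost path search over 26-connected
steps. Each step costs its physical length times the mean of the
brightness weights `1 + (I_max − I)/(I_max − I_min)` of its two voxels,
computed over a corridor (bounding box of the endpoints padded 1 µm), so
the path follows bright neck signal instead of cutting dark corners; the
weight averaging makes the cost symmetric and the search deterministic.
Following the neck definition, the final dendrite-border voxel is
dropped: the neck runs from the head edge to the voxel preceding the
dendrite. Where necks are not resolvable the per-run `straight_line`
mode instead reports the head-centroid-to-dendrite-surface distance as a
spine-length estimate. 2D (single-slice) images are accepted by
detection and segmentation but refused by the tracer.

**5. Measurements.** Head volume is voxel count × voxel volume; head
surface is the sum of exposed voxel-face areas — exact on blocks, and a
known ≈1.5× overestimate on smooth spheres (tested; a mesh-based area is
a possible extension, not the default). The result table carries one row
per spine (volume, surface, neck length, type, centroid, distance to
dendrite, edit provenance, truncation flag); the summary reports dendrite
length (sum of SWC segment lengths — by our convention the full imported
reconstruction, not only the imaged portion), spine count and density.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `intensity_min` | 50 | intensity | floor for automatic maxima (suits 0–255-range data) |
| `dist_min`, `dist_max` | 0.2, 2.5 | µm | search band around the dendrite border |
| `min_separation` | 0.5 | µm | greedy seed thinning radius |
| `smoothing_sigma` | off | µm | pre-smoothing for noisy stacks; set it to the PSF sigmas for a matched filter |
| `threshold_fraction` | 0.5 | – | fraction of seed-over-background contrast |
| `radius_max` | 1.5 | µm | cap on head extent and background-shell radius |
| `background_quantile` | 0.05 | – | shell quantile used as local background |
| `corridor_pad` | 1 | µm | padding of the neck-search corridor |

All are exposed in `detection_params()` / `segmentation_params()`, the
run config and the CLI, so a user can re-run any stage after changing
them — the workflow's intended correction loop, together with the edit
script (`add_seed`, `remove_seed`, `merge`, `remove_head`, `retrace`).

## What the phantom generator emulates

`phantom_spec()` + `render_phantom()` build a dendrite-plus-spines scene
with exhaustive ground truth: a straight 0.4 µm-radius shaft along x,
spines as head spheres (default radius 0.4 µm) on neck cylinders (default
0.12 µm radius) anchored on the shaft surface, stubby spines as heads
half-overlapping the shaft. Conditions mirror a high-resolution confocal
acquisition: 0.06 µm pixels, 0.2 µm z-steps, Gaussian PSF with 0.08 µm
lateral and 0.25 µm axial sigma, 8-bit-range intensity levels
(background 10, dendrite 200, neck 150, head 255), optional Poisson
photon noise and Gaussian readout noise with a fixed RNG seed (we quote
SNR as peak-over-background divided by the background sigma). Spines
whose surfaces would intersect raise an error so the truth stays
unambiguous.

The phantoms are deliberately idealized: real stacks have depth-dependent
PSFs, uneven labelling, touching spines from other dendrites, and
curved, tapering shafts. Passing the phantom suite therefore shows the
geometry, thresholding and path search are correct under known blur and
noise — not that the default parameters are optimal for any given
microscope.

One physical effect the phantoms do reproduce is worth flagging: a spine
whose neck points near the optical axis is smeared by the axial PSF
(0.25 µm sigma against 0.2 µm z-steps) until head, neck and shaft merge
into one suprathreshold bridge, so short near-axial spines classify as
stubby and their necks cannot be measured. This is a resolution limit of
the imaging geometry (the reason deconvolution is routinely recommended
upstream), so the quantitative neck-length and classification studies in
the test suite use laterally oriented spines with 1.0 µm necks — on
wider grids (96-voxel lateral extent) so the longer spines fit — and the
classification run raises `intensity_min` to 100, the workflow's own
false-positive control, because blur overlap between eight spines and
the shaft creates faint (~50-intensity) secondary maxima well separated
from true heads (~220).

## Numerical choices and degenerate inputs

* Voxel convention: 1-based indices, voxel `(i,j,k)` centred at
  `((i−0.5)dx, (j−0.5)dy, (k−0.5)dz)`; all geometry in µm.
* Plateau maxima, closest-pair ties, nearest-seed-deletion ties and the
  manual-add window all break ties lexicographically — every operation
  is deterministic, and a fixed config reproduces byte-identical
  outputs.
* The distance map sets dendrite-interior voxels to 0; the detection
  band additionally excludes interior voxels explicitly, so `dist_min = 0`
  remains meaningful.
* Heads touching the image boundary are kept but flagged `truncated`.
* An unreachable neck corridor (fully blocked) falls back to
  straight-line mode with a warning rather than failing the run.
* TIFF calibration: the reader honours ImageJ-style description and
  resolution tags; the bundled writer records spacing in a JSON sidecar
  (`<file>.tif.json`), since the linked TIFF library does not emit
  calibration tags. An explicit spacing override always wins.

## Problem sizes used in validation

The test suite validates each geometric primitive against brute-force
oracles (exhaustive nearest-surface search, quadratic greedy scans,
all-pairs border scans, Dijkstra on the full lattice) on a thousand
random instances with grids up to 15³, and the full pipeline on rendered
phantoms of 64×64×32 to 128×144×64 voxels — sizes at which the analytic
expectations (capsule and frustum volumes, sphere volumes, straight neck
lengths) are sharp while the whole suite stays quick. Detection is
scored on ten phantoms per noise condition (50 spines each). The same
phantom studies are what `scripts/acceptance.R` re-runs end to end.

## Known limitations

* Neck *width* is deliberately not estimated: it lies below the
  resolution of the data this pipeline targets.
* Spine classes beyond stubby/necked (thin vs mushroom, filopodia) are
  out of scope; the table's continuous measurements support whatever
  grouping the user prefers.
* The voxel-face surface estimator overestimates smooth surfaces by a
  known factor (≈1.5× on spheres); comparisons should use a single
  estimator consistently.
* Automated dendrite tracing is not included — the SWC model is an
  input, produced by any tracing tool.
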