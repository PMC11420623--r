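# spinemorph

3D detection, segmentation and morphometry of dendritic spines in
fluorescence microscopy stacks — as an R package with a scriptable
command-line interface.

Dendritic spines carry glutamatergic synapses: their density along a
dendrite measures connectivity, head volume correlates with synaptic
strength, and neck length modulates compartmentalization. `spinemorph`
takes a single-channel 3D stack (TIFF, with voxel spacing in µm) plus a
dendrite reconstruction in SWC format and produces a per-spine table of
head volume and surface, neck length, stubby/necked type, and
per-dendrite spine density. Everything an interactive tool would do with
mouse clicks is expressed as coordinate-based, replayable edit commands,
so every result is reproducible end to end.

## Method at a glance

1. **Dendrite realization** — the SWC node chain is rasterized as
   spheres joined by conical frustums (radius `r(t) = r₁ + t·(r₂ − r₁)`
   along each segment); an anisotropic Euclidean distance transform maps
   each voxel's distance to the dendrite border.
2. **Detection** — spine-head seeds are 26-neighbourhood regional maxima
   with intensity ≥ `intensity_min` inside the distance band
   `[dist_min, dist_max]`, thinned greedily to a minimum separation.
3. **Segmentation** — each seed grows through the connected region above
   its adaptive threshold `T = bg + f·(I_seed − bg)` (local background
   `bg` from a shell quantile, `f` = 0.5 by default), clipped to
   `radius_max` and split between competing seeds by proximity.
4. **Neck tracing** — for non-stubby spines, a minimum-cost path from
   the head border to the dendrite border over 26-connected steps
   weighted by `step length × (1 + (I_max − I)/(I_max − I_min))`,
   favouring bright neck signal; stubby = head in contact with the
   shaft. A straight-line mode covers stacks whose necks are invisible.
5. **Measurements** — head volume (voxel count × voxel volume), head
   surface (exposed voxel faces), neck length (sum of physical step
   lengths), spine density (count / dendrite length).

A synthetic-phantom module renders dendrite+spine scenes (anisotropic
Gaussian PSF, Poisson + Gaussian noise, exact ground truth) so the whole
pipeline is testable without real data.

## Worked example

Simulate a phantom with four necked spines (1 µm necks) and one stubby
spine, then run the full pipeline:

```r
library(spinemorph)

spines <- data.frame(position = seq(0.5, 5.26, length.out = 5),
                     angle = rep(c(0, pi), length.out = 5),
                     neck_length = 1.0, neck_radius = 0.12,
                     head_radius = 0.4, type = "necked")
spines$type[3] <- "stubby"; spines$neck_length[3] <- 0

ph <- render_phantom(phantom_spec(spines = spines, dims = c(96L, 80L, 32L)))
write_stack(ph$stack, "stack.tif")
write_swc(ph$model, "dendrite.swc")

res <- run_pipeline(list(stack = "stack.tif", swc = "dendrite.swc",
                         out_dir = "out"))
res$summary
#> dendrite: 5.700 um, 5 spines, density 0.8772 spines/um
res$records[, c("spine_id", "spine_type", "head_volume_um3",
                "head_surface_um2", "neck_length_um")]
#>   spine_id spine_type head_volume_um3 head_surface_um2 neck_length_um
#> 1        1     necked          0.2275            2.578           1.08
#> 2        2     necked          0.2275            2.578           1.08
#> 3        3     necked          0.2275            2.578           1.08
#> 4        4     necked          0.2275            2.578           1.08
#> 5        5     stubby          0.2131            2.390           0.00
```

All five spines are found (precision and recall 1 against the ground
truth), the four 1.0 µm necks measure 1.08 µm (within one voxel
diagonal, 0.22 µm at this spacing), the stubby spine is typed correctly
with neck length 0, and the head volumes sit within 15 % of the analytic
4/3·π·0.4³ ≈ 0.268 µm³ — the expected bias for a 0.4 µm sphere rendered
under a 0.25 µm axial PSF and 0.2 µm z-steps. `out/` now contains
`seeds.csv`, the head label stack `heads.tif`, `necks.csv`, a 4-channel
`overlay.tif` (image / dendrite / heads / necks), `spines.csv`,
`summary.json` and a `log.txt` recording every parameter and edit.

The same run from a shell:

```sh
Rscript inst/cli/spinemorph.R simulate --out sim --seed 3
Rscript inst/cli/spinemorph.R run --stack sim/stack.tif \
    --swc sim/dendrite.swc --out res
Rscript inst/cli/spinemorph.R evaluate --table res/spines.csv \
    --truth sim/truth.csv
```

Manual corrections go in an edit script (`--edit-script edits.txt`):

```
remove_seed 31 78 18     # delete the seed nearest this voxel
add_seed 54 12 16        # add a seed (snaps to the local 5x5 argmax)
merge 2 3                # merge two adjacent head objects
retrace 4 60 22 15       # re-trace neck 4 from a new border voxel
```

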