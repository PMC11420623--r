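# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default 5-spine noise-free phantom + its derived stages
fx_phantom <- function() cached("phantom", render_phantom(phantom_spec()))

fx_distance <- function() cached("distance", border_distance_map(fx_phantom()$volume))

fx_seeds <- function() cached("seeds", {
  ph <- fx_phantom()
  detect_local_maxima(ph$stack, fx_distance(), detection_params(),
                      ph$volume$mask)
})

fx_heads <- function() cached("heads", {
  ph <- fx_phantom()
  segment_heads(ph$stack, fx_seeds(), ph$volume)
})

fx_necks <- function() cached("necks", {
  ph <- fx_phantom()
  trace_all_necks(ph$stack, fx_heads(), ph$volume)
})

# classification phantom: 3 stubby + 5 necked, 1 um necks, wide grid.
# Azimuths lean lateral (alternating +/- y with moderate tilt): necks
# pointing near the optical axis smear into apparent shaft contact
# under the anisotropic PSF, which is a resolution limit rather than a
# classification property.
fx_class_phantom <- function() cached("class_phantom", {
  types <- c("stubby", "necked", "necked", "stubby", "necked", "necked",
             "stubby", "necked")
  spines <- spinemorph:::default_spine_layout(8, 96 * 0.06, types = types,
                                              neck_length = 1.0)
  spines$angle <- rep(c(0, pi), length.out = 8) +
    c(0.3, -0.3, 0.15, -0.15, -0.3, 0.3, -0.15, 0.15)
  render_phantom(phantom_spec(spines = spines, dims = c(96L, 96L, 32L)))
})

# laterally oriented straight 1 um necks (neck axis in the xy plane,
# where the PSF is narrow)
fx_neck_phantom <- function() cached("neck_phantom", {
  spines <- data.frame(position = seq(0.5, 5.26, length.out = 5),
                       angle = rep(c(0, pi), length.out = 5),
                       neck_length = 1.0, neck_radius = 0.12,
                       head_radius = 0.4, type = "necked")
  render_phantom(phantom_spec(spines = spines, dims = c(96L, 80L, 32L)))
})

run_stages <- function(ph, det = detection_params(),
                       seg = segmentation_params(), mode = "traced") {
  bd <- border_distance_map(ph$volume)
  seeds <- detect_local_maxima(ph$stack, bd, det, ph$volume$mask)
  heads <- segment_heads(ph$stack, seeds, ph$volume, seg)
  necks <- trace_all_necks(ph$stack, heads, ph$volume, mode = mode)
  list(bd = bd, seeds = seeds, heads = heads, necks = necks,
       table = spine_table(heads, necks))
}

seed_centers <- function(seeds, spacing) {
  voxel_center(as.matrix(seeds[, c("i", "j", "k")]), spacing)
}
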