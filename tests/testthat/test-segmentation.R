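test_that("rendered spherical heads are recovered within tolerance", {
  ph <- fx_phantom()
  heads <- fx_heads()
  vols <- head_volume(heads)
  true_vol <- 4 / 3 * pi * 0.4^3
  expect_equal(length(vols), nrow(ph$truth))
  for (v in vols) expect_lt(abs(v - true_vol) / true_vol, 0.30)
})

test_that("an isolated bright voxel segments to exactly one voxel", {
  a <- array(10, c(15L, 15L, 9L))
  a[3, 3, 3] <- 200 # dendrite stand-in far from the blob
  mask <- array(FALSE, dim(a))
  mask[12:14, 12:14, 7:9] <- TRUE
  vol <- structure(list(mask = mask, spacing = c(0.1, 0.1, 0.1),
                        origin = c(0, 0, 0),
                        border = spinemorph:::border_mask(mask)),
                   class = "dendrite_volume")
  a[8, 8, 5] <- 250
  st <- image_stack(a, c(0.1, 0.1, 0.1))
  seeds <- data.frame(i = 8L, j = 8L, k = 5L, intensity = 250,
                      origin = "automatic")
  h <- segment_heads(st, seeds, vol)
  expect_equal(h$info$n_voxels, 1L)
  expect_equal(unname(head_voxels(h, 1L)[1, ]), c(8L, 8L, 5L))
})

# one elongated flat-intensity blob so that two seeds inside it derive
# the same adaptive threshold (a double-maximum head)
double_seed_blob <- function() {
  sp <- c(0.06, 0.06, 0.2)
  a <- array(10, c(32L, 24L, 12L))
  ax <- lapply(1:3, function(q) (seq_len(dim(a)[q]) - 0.5) * sp[q])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  t <- pmin(pmax((g$x - 0.7) / 0.5, 0), 1)
  d2 <- (g$x - (0.7 + t * 0.5))^2 + (g$y - 0.7)^2 + (g$z - 1.2)^2
  a[array(d2 <= 0.2^2, dim(a))] <- 200
  mask <- array(FALSE, dim(a))
  mask[1:3, 20:24, 1:12] <- TRUE
  vol <- structure(list(mask = mask, spacing = sp, origin = c(0, 0, 0),
                        border = spinemorph:::border_mask(mask)),
                   class = "dendrite_volume")
  st <- image_stack(a, sp)
  seeds <- data.frame(i = c(12L, 20L), j = c(12L, 12L), k = c(6L, 6L),
                      intensity = 200, origin = "automatic")
  stopifnot(all(st$data[as.matrix(seeds[, 1:3])] == 200))
  list(stack = st, volume = vol, seeds = seeds)
}

test_that("two seeds in one head split it into adjacent disjoint objects", {
  fx <- double_seed_blob()
  h2 <- segment_heads(fx$stack, fx$seeds, fx$volume)
  expect_equal(nrow(h2$info), 2L)
  va <- head_voxels(h2, 1L)
  vb <- head_voxels(h2, 2L)
  # disjoint but 26-adjacent
  lin <- function(m) m[, 1] + 1000L * (m[, 2] + 1000L * m[, 3])
  expect_length(intersect(lin(va), lin(vb)), 0L)
  mask_a <- spinemorph:::mask_from_voxels(va, dim(fx$stack$data))
  touch <- spinemorph:::binary_dilate(mask_a,
                                      spinemorph:::neighbor_offsets(26L))
  expect_true(any(touch[vb]))
  # union equals the single-seed segmentation
  h1 <- segment_heads(fx$stack, fx$seeds[1, ], fx$volume)
  v1 <- head_voxels(h1, 1L)
  expect_setequal(lin(rbind(va, vb)), lin(v1))
})

test_that("merging the split objects restores the single-seed head", {
  fx <- double_seed_blob()
  h2 <- segment_heads(fx$stack, fx$seeds, fx$volume)
  na <- h2$info$n_voxels[1]
  nb <- h2$info$n_voxels[2]
  m <- merge_heads(h2, 1L, 2L)
  expect_equal(nrow(m$info), 1L)
  expect_equal(m$info$n_voxels, na + nb)
  expect_equal(sum(head_volume(m)), na * prod(m$spacing) +
                 nb * prod(m$spacing))
  expect_equal(m$info$provenance, "merged")
})

test_that("merging non-adjacent heads is allowed but noted", {
  h <- fx_heads()
  expect_message(m <- merge_heads(h, h$info$label[1], h$info$label[3]),
                 "non-adjacent")
  expect_match(m$info$note[m$info$label == h$info$label[1]],
               "non_adjacent_merge")
  expect_error(merge_heads(h, 1L, 99L), "unknown")
})

test_that("removing a head clears only its voxels", {
  h <- fx_heads()
  labs <- h$info$label
  before <- lapply(labs[-1], function(l) head_voxels(h, l))
  h2 <- remove_head(h, labs[1])
  expect_equal(nrow(h2$info), length(labs) - 1L)
  expect_false(any(h2$labels == labs[1]))
  after <- lapply(labs[-1], function(l) head_voxels(h2, l))
  expect_equal(after, before)
  expect_error(remove_head(h2, labs[1]), "no head")
})

test_that("removing every head leaves an empty label grid", {
  h <- fx_heads()
  for (l in h$info$label) h <- remove_head(h, l)
  expect_equal(sum(h$labels), 0L)
  expect_equal(nrow(h$info), 0L)
})

test_that("segmentation is deterministic and re-adding reproduces a head", {
  ph <- fx_phantom()
  seeds <- fx_seeds()
  h1 <- segment_heads(ph$stack, seeds, ph$volume)
  h2 <- segment_heads(ph$stack, seeds, ph$volume)
  expect_identical(h1$labels, h2$labels)
  # remove then re-add from the same seed voxel
  lab <- h1$info$label[2]
  vox_before <- head_voxels(h1, lab)
  seedv <- c(h1$info$seed_i[2], h1$info$seed_j[2], h1$info$seed_k[2])
  h3 <- remove_head(h1, lab)
  h4 <- add_head_at(ph$stack, seedv, ph$volume, heads = h3)
  new_lab <- max(h4$info$label)
  expect_equal(head_voxels(h4, new_lab), vox_before)
})

test_that("labels partition their voxels and avoid the dendrite", {
  ph <- fx_phantom()
  h <- fx_heads()
  expect_false(any(h$labels > 0L & ph$volume$mask))
  counts <- table(h$labels[h$labels > 0L])
  expect_equal(sort(as.integer(names(counts))), sort(h$info$label))
  expect_equal(unname(as.integer(counts[as.character(h$info$label)])),
               h$info$n_voxels)
  # each head is connected and contains its seed
  for (r in seq_len(nrow(h$info))) {
    vox <- head_voxels(h, h$info$label[r])
    seedv <- matrix(c(h$info$seed_i[r], h$info$seed_j[r], h$info$seed_k[r]), 1)
    expect_true(any(vox[, 1] == seedv[1] & vox[, 2] == seedv[2] &
                      vox[, 3] == seedv[3]))
    m <- spinemorph:::mask_from_voxels(vox, dim(h$labels))
    comp <- spinemorph:::flood_fill(m, seedv, 26L)
    expect_equal(sum(comp), nrow(vox))
  }
})

test_that("raising the threshold fraction never grows a head", {
  ph <- fx_phantom()
  seeds <- fx_seeds()
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
    h <- segment_heads(ph$stack, seeds, ph$volume,
                       segmentation_params(threshold_fraction = f))
    sum(h$info$n_voxels)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("seeds inside the dendrite are skipped with a warning", {
  ph <- fx_phantom()
  inside <- which(ph$volume$mask, arr.ind = TRUE)[1, ]
  seeds <- rbind(fx_seeds(),
                 data.frame(i = inside[1], j = inside[2], k = inside[3],
                            intensity = 200, origin = "automatic"))
  expect_warning(h <- segment_heads(ph$stack, seeds, ph$volume),
                 "inside the dendrite")
  expect_equal(nrow(h$info), nrow(fx_seeds()))
})

test_that("manual head addition recovers an undetected head", {
  ph <- fx_phantom()
  seeds <- fx_seeds()
  h <- segment_heads(ph$stack, seeds[-1, ], ph$volume)
  click <- c(seeds$i[1] + 1L, seeds$j[1] - 1L, seeds$k[1])
  h2 <- add_head_at(ph$stack, click, ph$volume, heads = h)
  new_lab <- max(h2$info$label)
  vol <- head_volume(h2, new_lab)
  true_vol <- 4 / 3 * pi * 0.4^3
  expect_lt(abs(vol - true_vol) / true_vol, 0.30)
  # object contains the derived seed voxel
  info <- h2$info[h2$info$label == new_lab, ]
  expect_equal(h2$labels[matrix(c(info$seed_i, info$seed_j, info$seed_k), 1)],
               new_lab)
  expect_equal(info$provenance, "manual")
})

test_that("clicking on background yields a tiny low-contrast-flagged object", {
  ph <- fx_phantom()
  h <- add_head_at(ph$stack, c(3L, 3L, 3L), ph$volume)
  expect_equal(h$info$n_voxels, 1L)
  expect_equal(h$info$note, "low_intensity")
  inside <- which(ph$volume$mask, arr.ind = TRUE)[1, ]
  expect_error(add_head_at(ph$stack, inside, ph$volume), "inside the dendrite")
})

test_that("volume recovery error shrinks when the grid is refined", {
  one_spine <- function(spacing, dims) {
    spines <- data.frame(position = dims[1] * spacing[1] / 2, angle = 0,
                         neck_length = 1.0, neck_radius = 0.12,
                         head_radius = 0.4, type = "necked")
    render_phantom(phantom_spec(spines = spines, dims = dims,
                                spacing = spacing))
  }
  vol_err <- function(ph) {
    st <- run_stages(ph)
    abs(head_volume(st$heads)[1] - 4 / 3 * pi * 0.4^3) / (4 / 3 * pi * 0.4^3)
  }
  e_coarse <- vol_err(one_spine(c(0.06, 0.06, 0.2), c(64L, 72L, 32L)))
  e_fine <- vol_err(one_spine(c(0.03, 0.03, 0.1), c(128L, 144L, 64L)))
  expect_lt(e_coarse, 0.30)
  expect_lt(e_fine, e_coarse)
})
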