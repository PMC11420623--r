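# small synthetic scene: a dendrite slab and a detached cubic "head"
slab_scene <- function(gap_vox = 4L, sp = c(0.1, 0.1, 0.1)) {
  d <- c(15L, 3L + gap_vox + 6L, 15L)
  dend <- array(FALSE, d)
  dend[, 1:3, ] <- TRUE
  head <- array(FALSE, d)
  head[7:9, (3L + gap_vox + 1L):(3L + gap_vox + 3L), 7:9] <- TRUE
  vol <- structure(list(mask = dend, spacing = sp, origin = c(0, 0, 0),
                        border = spinemorph:::border_mask(dend)),
                   class = "dendrite_volume")
  img <- array(10, d)
  img[head] <- 200
  img[dend] <- 200
  # bright straight corridor between head and dendrite
  img[8, 4:(3L + gap_vox), 8] <- 180
  list(volume = vol, head = head, stack = image_stack(img, sp))
}

test_that("closest border pair matches geometry and the exhaustive scan", {
  sc <- slab_scene(gap_vox = 4L)
  pair <- closest_border_pair(sc$head, sc$volume, sc$stack$spacing)
  want <- oracle_closest_pair(sc$head, sc$volume$mask, sc$stack$spacing)
  expect_equal(pair$distance, want$distance)
  expect_equal(pair$distance, 0.5) # 5 voxel steps of 0.1 um, centre to centre
})

test_that("closest border pair matches the oracle on random blobs", {
  set.seed(31)
  for (trial in 1:10) {
    d <- c(10L, 10L, 8L)
    sp <- runif(3, 0.05, 0.25)
    dend <- array(FALSE, d)
    dend[, 1:2, ] <- TRUE
    head <- array(FALSE, d)
    ctr <- c(sample(3:8, 1), sample(5:8, 1), sample(3:6, 1))
    for (q in 1:4) {
      v <- pmin(pmax(ctr + sample(-1:1, 3, TRUE), 1L), d)
      if (v[2] > 3) head[v[1], v[2], v[3]] <- TRUE
    }
    head[ctr[1], ctr[2], ctr[3]] <- TRUE
    vol <- structure(list(mask = dend, spacing = sp, origin = c(0, 0, 0),
                          border = spinemorph:::border_mask(dend)),
                     class = "dendrite_volume")
    pair <- closest_border_pair(head, vol, sp)
    want <- oracle_closest_pair(head, dend, sp)
    expect_equal(pair$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("a bright straight tube is traced at its true length", {
  sc <- slab_scene(gap_vox = 10L) # 1.0 um gap
  pair <- closest_border_pair(sc$head, sc$volume, sc$stack$spacing)
  np <- trace_neck(sc$stack, pair$head_voxel, pair$dendrite_voxel, sc$head,
                   sc$volume$mask)
  expect_equal(np$mode, "traced")
  # head-border start to voxel preceding the dendrite: 1.0 um, within
  # one voxel diagonal
  expect_lt(abs(np$length - 1.0), sqrt(sum(sc$stack$spacing^2)))
  # invariants: 26-connected steps, no voxel in head (beyond the start)
  # or dendrite
  steps <- diff(np$voxels)
  expect_true(all(abs(steps) <= 1L))
  expect_false(any(sc$volume$mask[np$voxels]))
  expect_false(any(sc$head[np$voxels[-1, , drop = FALSE]]))
  expect_true(sc$head[matrix(np$voxels[1, ], 1)])
})

test_that("the path follows a bright corridor instead of a dark shortcut", {
  sp <- c(0.1, 0.1, 0.1)
  d <- c(9L, 9L, 3L)
  img <- array(10, d)
  # L-shaped bright corridor from (2,2) to (8,8) via (8,2)
  img[2:8, 2, 2] <- 200
  img[8, 2:8, 2] <- 200
  st <- image_stack(img, sp)
  head_mask <- array(FALSE, d); head_mask[2, 2, 2] <- TRUE
  dend_mask <- array(FALSE, d); dend_mask[8, 8, 2] <- TRUE
  np <- trace_neck(st, c(2L, 2L, 2L), c(8L, 8L, 2L), head_mask, dend_mask)
  # the pure diagonal would leave 7 voxels after the endpoint drop; the
  # corridor detour is longer but cheaper under the brightness weight
  expect_gte(nrow(np$voxels), 11L)
  on_corridor <- img[np$voxels] == 200
  expect_true(all(on_corridor))
})

test_that("traced cost equals the exhaustive lowest-cost oracle", {
  set.seed(77)
  sp <- c(0.08, 0.1, 0.2)
  for (trial in 1:5) {
    d <- c(6L, 6L, 5L)
    img <- array(runif(prod(d), 10, 250), d)
    start <- c(1L, 1L, 1L)
    end <- c(6L, 6L, 5L)
    head_mask <- array(FALSE, d); head_mask[matrix(start, 1)] <- TRUE
    dend_mask <- array(FALSE, d); dend_mask[matrix(end, 1)] <- TRUE
    st <- image_stack(img, sp)
    np <- trace_neck(st, start, end, head_mask, dend_mask, corridor_pad = 5)
    got_cost <- path_cost(img, sp, rbind(np$voxels, end))
    want_cost <- oracle_path_cost(img, sp, start, end)
    expect_equal(got_cost, want_cost, tolerance = 1e-10)
  }
})

test_that("path cost never exceeds the straight voxel line's cost", {
  set.seed(13)
  sp <- c(0.06, 0.06, 0.2)
  d <- c(8L, 8L, 6L)
  img <- array(runif(prod(d), 10, 250), d)
  start <- c(2L, 2L, 2L); end <- c(7L, 7L, 5L)
  head_mask <- array(FALSE, d); head_mask[matrix(start, 1)] <- TRUE
  dend_mask <- array(FALSE, d); dend_mask[matrix(end, 1)] <- TRUE
  np <- trace_neck(image_stack(img, sp), start, end, head_mask, dend_mask,
                   corridor_pad = 3)
  # Bresenham-ish straight line between the endpoints
  nsteps <- max(abs(end - start))
  line <- cbind(round(seq(start[1], end[1], length.out = nsteps + 1)),
                round(seq(start[2], end[2], length.out = nsteps + 1)),
                round(seq(start[3], end[3], length.out = nsteps + 1)))
  expect_lte(path_cost(img, sp, rbind(np$voxels, end)),
             path_cost(img, sp, line) + 1e-12)
})

test_that("blocked corridors fall back to straight-line mode", {
  d <- c(9L, 9L, 5L)
  img <- array(50, d)
  start <- c(2L, 2L, 2L)
  end <- c(8L, 8L, 4L)
  # every voxel except the two endpoints belongs to the head mask, so
  # no connecting step is admissible
  head_mask <- array(TRUE, d)
  head_mask[matrix(end, 1)] <- FALSE
  dend_mask <- array(FALSE, d)
  dend_mask[matrix(end, 1)] <- TRUE
  expect_warning(
    np <- trace_neck(image_stack(img, c(0.1, 0.1, 0.2)), start, end,
                     head_mask, dend_mask),
    "straight-line")
  expect_equal(np$mode, "straight_line")
  expect_equal(np$length, sqrt(sum(((end - start) * c(0.1, 0.1, 0.2))^2)))
})

test_that("straight-line spine length matches the brute-force minimum", {
  sc <- slab_scene(gap_vox = 6L)
  got <- straight_line_length(sc$head, sc$volume, sc$stack$spacing)
  hb <- which(sc$head, arr.ind = TRUE)
  centroid <- colMeans((hb - 0.5) %*% diag(sc$stack$spacing))
  db <- which(oracle_border(sc$volume$mask), arr.ind = TRUE)
  want <- min(apply(db, 1, function(v) {
    sqrt(sum(((v - 0.5) * sc$stack$spacing - centroid)^2))
  }))
  expect_equal(got, want)
})

test_that("contact classification separates stubby from necked", {
  sc <- slab_scene(gap_vox = 4L)
  expect_equal(classify_stubby(sc$head, sc$volume), "necked")
  touching <- array(FALSE, dim(sc$head))
  touching[7:9, 4:6, 7:9] <- TRUE # face-adjacent to the slab at j = 3
  expect_equal(classify_stubby(touching, sc$volume), "stubby")
  # corner-only contact: single-voxel dendrite, diagonally offset head
  dend1 <- array(FALSE, c(7L, 7L, 7L))
  dend1[4, 4, 4] <- TRUE
  vol1 <- structure(list(mask = dend1, spacing = sc$stack$spacing,
                         origin = c(0, 0, 0),
                         border = spinemorph:::border_mask(dend1)),
                    class = "dendrite_volume")
  diag_touch <- array(FALSE, c(7L, 7L, 7L))
  diag_touch[5, 5, 5] <- TRUE
  expect_equal(classify_stubby(diag_touch, vol1), "stubby")
  expect_equal(classify_stubby(diag_touch, vol1, connectivity = 6L),
               "necked")
})

test_that("phantom stubby/necked classification is exact", {
  ph <- fx_class_phantom()
  st <- run_stages(ph, det = detection_params(intensity_min = 100))
  centers <- seed_centers(st$seeds, ph$stack$spacing)
  expect_equal(nrow(st$seeds), 8L)
  # match each seed to its ground-truth spine
  truth_xyz <- as.matrix(ph$truth[, c("center_x_um", "center_y_um",
                                      "center_z_um")])
  seed_info <- st$heads$info
  for (r in seq_len(nrow(st$table))) {
    lab <- st$table$spine_id[r]
    q <- which(seed_info$label == lab)
    p <- voxel_center(c(seed_info$seed_i[q], seed_info$seed_j[q],
                        seed_info$seed_k[q]), ph$stack$spacing)
    truth_id <- which.min(colSums((t(truth_xyz) - as.numeric(p))^2))
    expect_equal(st$table$spine_type[r], ph$truth$type[truth_id])
    if (st$table$spine_type[r] == "stubby") {
      expect_equal(st$table$neck_length_um[r], 0)
    }
  }
})

test_that("neck-length recovery on straight 1 um necks is voxel-accurate", {
  ph <- fx_neck_phantom()
  st <- run_stages(ph)
  expect_equal(nrow(st$table), 5L)
  errs <- st$table$neck_length_um - 1.0
  expect_lt(max(abs(errs)), sqrt(sum(ph$stack$spacing^2)))
  expect_lte(sqrt(mean(errs^2)), max(ph$stack$spacing))
})

test_that("retracing from the original start reproduces the path", {
  sc <- slab_scene(gap_vox = 8L)
  pair <- closest_border_pair(sc$head, sc$volume, sc$stack$spacing)
  np1 <- trace_neck(sc$stack, pair$head_voxel, pair$dendrite_voxel, sc$head,
                    sc$volume$mask)
  np2 <- retrace_neck(sc$stack, sc$head, pair$head_voxel, sc$volume)
  expect_equal(np2$voxels, np1$voxels)
  expect_equal(np2$length, np1$length)
})

test_that("retracing from the far side gives a longer, valid path", {
  sc <- slab_scene(gap_vox = 8L)
  pair <- closest_border_pair(sc$head, sc$volume, sc$stack$spacing)
  hb <- which(spinemorph:::border_mask(sc$head), arr.ind = TRUE)
  far <- hb[which.max(hb[, 2]), ] # far side of the head
  np_far <- retrace_neck(sc$stack, sc$head, far, sc$volume)
  np_near <- trace_neck(sc$stack, pair$head_voxel, pair$dendrite_voxel,
                        sc$head, sc$volume$mask)
  expect_gt(np_far$length, np_near$length)
  # still ends adjacent to the dendrite
  last <- np_far$voxels[nrow(np_far$voxels), ]
  nb <- spinemorph:::binary_dilate(sc$volume$mask,
                                   spinemorph:::neighbor_offsets(26L))
  expect_true(nb[matrix(last, 1)])
  expect_error(retrace_neck(sc$stack, sc$head, c(1L, 14L, 1L), sc$volume),
               "border")
})

test_that("neck length is at least the border gap minus one diagonal", {
  ph <- fx_neck_phantom()
  st <- run_stages(ph)
  diag <- sqrt(sum(ph$stack$spacing^2))
  for (r in seq_len(nrow(st$table))) {
    expect_gte(st$table$neck_length_um[r],
               st$table$distance_to_dendrite_um[r] - diag)
  }
})

test_that("neck tracing refuses single-slice stacks", {
  a <- array(10, c(8L, 8L, 1L))
  st <- image_stack(a, c(0.1, 0.1, 0.2))
  mask <- array(FALSE, dim(a)); mask[, 1:2, ] <- TRUE
  vol <- structure(list(mask = mask, spacing = st$spacing,
                        origin = c(0, 0, 0),
                        border = spinemorph:::border_mask(mask)),
                   class = "dendrite_volume")
  expect_error(trace_neck(st, c(4L, 6L, 1L), c(4L, 2L, 1L),
                          array(FALSE, dim(a)), mask), "3D")
})
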