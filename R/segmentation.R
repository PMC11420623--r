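#' Segmentation parameters
#'
#' Spine heads are grown from each seed by an adaptive fractional
#' threshold on the intensity distribution around the local maximum:
#' a per-seed threshold `T = bg + threshold_fraction * (I_seed - bg)`
#' with the local background `bg` estimated as a low quantile of the
#' intensities on a thin shell of radius `radius_max` around the seed.
#' The head is the connected component of `{I >= T}` containing the
#' seed, clipped to `radius_max` and to voxels outside the dendrite.
#'
#' @param threshold_fraction fraction in (0, 1) of the seed-over-
#'   background contrast that voxels must reach to join (default 0.5,
#'   i.e. the local half-maximum - the usual operating point for
#'   diffraction-limited bright blobs).
#' @param radius_max cap on head extent from the seed, micrometres
#'   (default 1.5, generously above common head radii).
#' @param connectivity 6 or 26 (default 26).
#' @param background_quantile quantile of the shell intensities used as
#'   local background (default 0.05).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_fraction = 0.5, radius_max = 1.5,
                                connectivity = 26L,
                                background_quantile = 0.05) {
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  if (radius_max <= 0) stop("radius_max must be > 0", call. = FALSE)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26",
                                          call. = FALSE)
  if (!(background_quantile >= 0 && background_quantile <= 0.5)) {
    stop("background_quantile must be in [0, 0.5]", call. = FALSE)
  }
  structure(list(threshold_fraction = threshold_fraction,
                 radius_max = radius_max,
                 connectivity = as.integer(connectivity),
                 background_quantile = background_quantile),
            class = "segmentation_params")
}

# Grow one head from a seed. Returns linear voxel indices (global grid)
# plus the background estimate, or NULL when the seed sits inside the
# dendrite. `blocked` is an optional logical array of voxels that may
# not be claimed (already-labelled heads, for manual additions).
grow_head <- function(data, spacing, seed, volume, params, blocked = NULL) {
  d <- dim(data)
  seed <- as.integer(seed)
  if (volume$mask[matrix(seed, 1L)]) return(NULL)
  half <- ceiling(params$radius_max / spacing)
  lo <- pmax(seed - half, 1L)
  hi <- pmin(seed + half, d)
  ii <- lo[1L]:hi[1L]; jj <- lo[2L]:hi[2L]; kk <- lo[3L]:hi[3L]
  sub <- data[ii, jj, kk, drop = FALSE]
  sd3 <- c(length(ii), length(jj), length(kk))
  dim(sub) <- sd3

  cx <- (ii - 0.5) * spacing[1L] - (seed[1L] - 0.5) * spacing[1L]
  cy <- (jj - 0.5) * spacing[2L] - (seed[2L] - 0.5) * spacing[2L]
  cz <- (kk - 0.5) * spacing[3L] - (seed[3L] - 0.5) * spacing[3L]
  dist2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  dim(dist2) <- sd3

  shell <- dist2 > (params$radius_max - max(spacing))^2 &
    dist2 <= params$radius_max^2
  bg <- if (any(shell)) {
    as.numeric(quantile(sub[shell], params$background_quantile, names = FALSE))
  } else {
    min(sub)
  }
  iseed <- data[matrix(seed, 1L)]
  thr <- bg + params$threshold_fraction * (iseed - bg)

  # voxels at or below the local background never join: keeps the
  # degenerate flat-background click from flooding its plateau (the
  # epsilon absorbs float jitter on constant regions)
  bg_eps <- bg + 1e-9 * max(abs(bg), 1)
  dmask <- volume$mask[ii, jj, kk]
  dim(dmask) <- sd3
  allowed <- sub >= thr & sub > bg_eps & dist2 <= params$radius_max^2 &
    !dmask
  dim(allowed) <- sd3
  if (!is.null(blocked)) {
    blk <- blocked[ii, jj, kk]
    dim(blk) <- sd3
    allowed <- allowed & !blk
  }
  seed_local <- matrix(seed - lo + 1L, 1L)
  allowed[seed_local] <- TRUE
  comp <- flood_fill(allowed, seed_local, params$connectivity)
  idx_local <- arrayInd(which(comp), sd3)
  idx <- sweep(idx_local, 2L, lo - 1L, "+")
  list(lin = idx[, 1L] + d[1L] * (idx[, 2L] - 1L + d[2L] * (idx[, 3L] - 1L)),
       background = bg, seed_intensity = iseed)
}

# A seed whose contrast over the local background is a sliver of the
# image dynamic range is almost certainly a background click; flag it.
low_contrast <- function(iseed, bg, imax) {
  (iseed - bg) <= 0.02 * max(imax - bg, .Machine$double.eps)
}

#' Segment spine heads around detected seeds
#'
#' Each seed grows into one 3D object (see [segmentation_params()] for
#' the growth rule). Voxels claimable by several heads are assigned to
#' the head whose seed is physically nearest (watershed-style split), so
#' two maxima inside one large head yield two adjacent, disjoint objects
#' that can later be merged with [merge_heads()]. After the split each
#' head keeps the connected component containing its seed. Seeds lying
#' inside the dendrite mask are skipped with a warning. Heads touching
#' the grid boundary are kept but flagged `truncated`; heads grown from
#' a seed at or below the local background are flagged `low_intensity`.
#'
#' @param image an `image_stack`.
#' @param seeds seed data.frame from [detect_local_maxima()] /
#'   [add_seed_at()].
#' @param volume a `dendrite_volume` on the same grid.
#' @param params a `segmentation_params` object.
#' @return a `spine_heads` object: list with `labels` (integer array,
#'   0 = unlabelled), `info` (one row per head: `label`, seed voxel,
#'   `seed_intensity`, `provenance`, `truncated`, `note`, `n_voxels`,
#'   `merged_from`), and `spacing`.
#' @export
segment_heads <- function(image, seeds, volume, params = segmentation_params()) {
  stopifnot(inherits(image, "image_stack"),
            inherits(volume, "dendrite_volume"),
            inherits(params, "segmentation_params"))
  if (is.null(seeds) || nrow(seeds) == 0L) {
    stop("no seeds to segment", call. = FALSE)
  }
  d <- dim(image$data)
  grown <- list()
  info <- list()
  label <- 0L
  for (r in seq_len(nrow(seeds))) {
    seed <- c(seeds$i[r], seeds$j[r], seeds$k[r])
    g <- grow_head(image$data, image$spacing, seed, volume, params)
    if (is.null(g)) {
      warning(sprintf("seed at (%d, %d, %d) lies inside the dendrite; skipped",
                      seed[1L], seed[2L], seed[3L]), call. = FALSE)
      next
    }
    label <- label + 1L
    grown[[label]] <- g
    info[[label]] <- data.frame(
      label = label, seed_i = seed[1L], seed_j = seed[2L], seed_k = seed[3L],
      seed_intensity = g$seed_intensity,
      provenance = if (identical(seeds$origin[r], "manual")) "manual"
                   else "automatic",
      truncated = FALSE,
      note = if (low_contrast(g$seed_intensity, g$background,
                              max(image$data))) "low_intensity" else "",
      n_voxels = 0L, merged_from = "")
  }
  if (label == 0L) stop("all seeds were inside the dendrite", call. = FALSE)
  info <- do.call(rbind, info)
  heads <- structure(list(labels = resolve_claims(grown, info, d,
                                                  image$spacing,
                                                  params$connectivity),
                          info = info, spacing = image$spacing),
                     class = "spine_heads")
  refresh_head_info(heads)
}

# Assign contested voxels to the nearest seed (ties to the lower label),
# then keep, per head, only the connected component containing its seed.
resolve_claims <- function(grown, info, d, spacing, connectivity) {
  labels <- array(0L, d)
  all_lin <- unlist(lapply(grown, `[[`, "lin"))
  all_lab <- rep(info$label, vapply(grown, function(g) length(g$lin), 0L))
  dup_lin <- unique(all_lin[duplicated(all_lin)])
  if (length(dup_lin) > 0L) {
    contested <- all_lin %in% dup_lin
    seed_pos <- voxel_center(as.matrix(info[, c("seed_i", "seed_j", "seed_k")]),
                             spacing)
    cl <- all_lin[contested]
    cb <- all_lab[contested]
    vox <- arrayInd(cl, d)
    pos <- voxel_center(vox, spacing)
    dist <- sqrt(rowSums((pos - seed_pos[match(cb, info$label), ,
                                         drop = FALSE])^2))
    o <- order(cl, dist, cb)
    winner <- !duplicated(cl[o])
    drop_idx <- which(contested)[o][!winner]
    all_lin <- all_lin[-drop_idx]
    all_lab <- all_lab[-drop_idx]
  }
  labels[all_lin] <- all_lab
  # reconnect: a nearest-seed split can strand voxels; keep the seed's
  # component only
  for (r in seq_len(nrow(info))) {
    lab <- info$label[r]
    own <- labels == lab
    seed <- matrix(c(info$seed_i[r], info$seed_j[r], info$seed_k[r]), 1L)
    comp <- flood_fill(own, seed, connectivity)
    labels[own & !comp] <- 0L
  }
  labels
}

# Recompute per-head voxel counts and the truncation flag.
refresh_head_info <- function(heads) {
  d <- dim(heads$labels)
  info <- heads$info
  for (r in seq_len(nrow(info))) {
    lin <- which(heads$labels == info$label[r])
    info$n_voxels[r] <- length(lin)
    idx <- arrayInd(lin, d)
    info$truncated[r] <- any(idx[, 1L] %in% c(1L, d[1L]) |
                               idx[, 2L] %in% c(1L, d[2L]) |
                               idx[, 3L] %in% c(1L, d[3L]))
  }
  heads$info <- info
  heads
}

#' Voxel indices of one head
#'
#' @param heads a `spine_heads` object.
#' @param label head label.
#' @return n x 3 integer matrix of voxel indices.
#' @export
head_voxels <- function(heads, label) {
  if (!label %in% heads$info$label) {
    stop(sprintf("no head with label %s", label), call. = FALSE)
  }
  arrayInd(which(heads$labels == label), dim(heads$labels))
}

#' Merge two spine heads
#'
#' The two objects become one (label of the first argument); useful when
#' one large head produced two maxima and hence two adjacent objects.
#' Merging non-adjacent heads is permitted but noted, since it usually
#' indicates an editing mistake.
#'
#' @param heads a `spine_heads` object.
#' @param label_a,label_b labels to merge (result keeps `label_a`).
#' @return the updated `spine_heads` object.
#' @export
merge_heads <- function(heads, label_a, label_b) {
  info <- heads$info
  if (!all(c(label_a, label_b) %in% info$label)) {
    stop("unknown head label in merge", call. = FALSE)
  }
  if (label_a == label_b) stop("cannot merge a head with itself",
                               call. = FALSE)
  vb <- head_voxels(heads, label_b)
  mask_a <- heads$labels == label_a
  adjacent <- any(binary_dilate(mask_a, neighbor_offsets(26L))[vb])
  heads$labels[heads$labels == label_b] <- as.integer(label_a)
  ra <- which(info$label == label_a)
  rb <- which(info$label == label_b)
  info$provenance[ra] <- "merged"
  prev <- info$merged_from[ra]
  info$merged_from[ra] <- paste(c(if (nzchar(prev)) prev, label_a, label_b,
                                  if (nzchar(info$merged_from[rb]))
                                    info$merged_from[rb]),
                                collapse = "+")
  if (!adjacent) {
    info$note[ra] <- paste(c(if (nzchar(info$note[ra])) info$note[ra],
                             "non_adjacent_merge"), collapse = ";")
    message(sprintf("merged non-adjacent heads %s and %s", label_a, label_b))
  }
  heads$info <- info[-rb, , drop = FALSE]
  rownames(heads$info) <- NULL
  refresh_head_info(heads)
}

#' Remove a spine head
#'
#' @param heads a `spine_heads` object.
#' @param label label of the head to remove; its voxels are cleared and
#'   all other labels are left unchanged.
#' @return the updated `spine_heads` object.
#' @export
remove_head <- function(heads, label) {
  if (!label %in% heads$info$label) {
    stop(sprintf("no head with label %s", label), call. = FALSE)
  }
  heads$labels[heads$labels == label] <- 0L
  heads$info <- heads$info[heads$info$label != label, , drop = FALSE]
  rownames(heads$info) <- NULL
  heads
}

#' Add a spine head manually at a position
#'
#' Creates a manual seed with [add_seed_at()] (exempt from the detection
#' criteria) and grows it with the standard rule; voxels already claimed
#' by existing heads are not taken.
#'
#' @param image an `image_stack`.
#' @param position voxel index triple inside the grid (must not lie
#'   inside the dendrite mask).
#' @param volume a `dendrite_volume`.
#' @param params a `segmentation_params` object.
#' @param heads optional existing `spine_heads` to extend.
#' @return the updated (or newly created) `spine_heads` object.
#' @export
add_head_at <- function(image, position, volume,
                        params = segmentation_params(), heads = NULL) {
  seed_row <- add_seed_at(image, position)
  seed <- c(seed_row$i, seed_row$j, seed_row$k)
  if (volume$mask[matrix(as.integer(position), 1L)] ||
        volume$mask[matrix(seed, 1L)]) {
    stop("position lies inside the dendrite mask", call. = FALSE)
  }
  blocked <- if (!is.null(heads)) heads$labels > 0L else NULL
  g <- grow_head(image$data, image$spacing, seed, volume, params, blocked)
  label <- if (is.null(heads)) 1L else max(0L, heads$info$label) + 1L
  row <- data.frame(label = label, seed_i = seed[1L], seed_j = seed[2L],
                    seed_k = seed[3L], seed_intensity = g$seed_intensity,
                    provenance = "manual", truncated = FALSE,
                    note = if (low_contrast(g$seed_intensity, g$background,
                                            max(image$data)))
                      "low_intensity" else "",
                    n_voxels = 0L, merged_from = "")
  if (is.null(heads)) {
    heads <- structure(list(labels = array(0L, dim(image$data)), info = row,
                            spacing = image$spacing),
                       class = "spine_heads")
  } else {
    heads$info <- rbind(heads$info, row)
  }
  heads$labels[g$lin] <- label
  rownames(heads$info) <- NULL
  refresh_head_info(heads)
}

#' @export
print.spine_heads <- function(x, ...) {
  cat(sprintf("spine_heads: %d heads, %d labelled voxels\n",
              nrow(x$info), sum(x$labels > 0L)))
  invisible(x)
}
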