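#' Detection parameters
#'
#' @param intensity_min intensity value below which local maxima are
#'   ignored (same units as the image; default 50, suited to data in the
#'   0-255 range).
#' @param dist_min,dist_max distance band in micrometres from the
#'   dendrite border delimiting the 3D search region; candidate maxima
#'   outside `[dist_min, dist_max]` are ignored (this is what excludes
#'   bright spines belonging to a neighbouring dendrite).
#' @param min_separation minimal physical distance in micrometres imposed
#'   between retained maxima; shrink for dense spines, expand for sparse.
#' @param smoothing_sigma optional Gaussian pre-smoothing sigma in
#'   micrometres (scalar or per-axis triple), default off. Local-maxima
#'   detection is noise sensitive; enable this (or denoise upstream) for
#'   low-SNR stacks.
#' @return a `detection_params` list.
#' @export
detection_params <- function(intensity_min = 50, dist_min = 0.2,
                             dist_max = 2.5, min_separation = 0.5,
                             smoothing_sigma = NULL) {
  if (!(dist_min >= 0 && dist_min < dist_max)) {
    stop("need 0 <= dist_min < dist_max", call. = FALSE)
  }
  if (min_separation < 0) stop("min_separation must be >= 0", call. = FALSE)
  structure(list(intensity_min = intensity_min, dist_min = dist_min,
                 dist_max = dist_max, min_separation = min_separation,
                 smoothing_sigma = smoothing_sigma),
            class = "detection_params")
}

empty_seeds <- function() {
  data.frame(i = integer(), j = integer(), k = integer(),
             intensity = numeric(), origin = character())
}

#' Detect spine-head seeds as 3D local maxima near the dendrite
#'
#' A voxel is a candidate if it is a regional maximum of its
#' 26-neighbourhood: no neighbour is brighter, and its iso-intensity
#' plateau (26-connected component of equal value) has no brighter
#' neighbour anywhere. A plateau contributes a single seed, the
#' lexicographically smallest (by `i`, then `j`, then `k`) of its voxels
#' that satisfies the constraints. Candidates must lie inside the
#' distance band, at or above `intensity_min`, and outside the dendrite
#' mask; survivors are sorted by decreasing intensity and thinned by
#' [filter_by_separation()].
#'
#' When `smoothing_sigma` is set, maxima, the intensity criterion and the
#' reported seed intensity are all evaluated on the smoothed image.
#'
#' @param image an `image_stack`.
#' @param border_distance distance map from [border_distance_map()], on
#'   the same grid.
#' @param params a `detection_params` object.
#' @param dendrite_mask optional logical array of dendrite-interior
#'   voxels to exclude (pass `volume$mask`).
#' @return data.frame of seeds: `i, j, k, intensity, origin`, sorted by
#'   decreasing intensity (ties broken lexicographically).
#' @export
detect_local_maxima <- function(image, border_distance, params,
                                dendrite_mask = NULL) {
  stopifnot(inherits(image, "image_stack"),
            inherits(params, "detection_params"))
  a <- image$data
  if (!identical(dim(a), dim(border_distance))) {
    stop("image and border-distance grids differ", call. = FALSE)
  }
  if (!is.null(params$smoothing_sigma)) {
    a <- gaussian_blur3d(a, params$smoothing_sigma, image$spacing)
  }
  d <- dim(a)
  nm <- neighborhood_max(a)
  in_band <- border_distance >= params$dist_min &
    border_distance <= params$dist_max & a >= params$intensity_min
  if (!is.null(dendrite_mask)) in_band <- in_band & !dendrite_mask

  cand_lin <- which(a >= nm & in_band)
  if (length(cand_lin) == 0L) return(empty_seeds())
  cand_idx <- arrayInd(cand_lin, d)

  eq_plateau <- a == nm # candidate touches an equal-valued neighbour
  visited <- array(FALSE, d)
  keep <- matrix(integer(), 0L, 3L)
  ord <- lex_order(cand_idx)
  for (r in ord) {
    li <- cand_lin[r]
    if (visited[li]) next
    if (!eq_plateau[li]) {
      # isolated strict maximum
      keep <- rbind(keep, cand_idx[r, , drop = FALSE])
      visited[li] <- TRUE
      next
    }
    plateau <- flood_fill(a == a[li], cand_idx[r, , drop = FALSE], 26L)
    plat_lin <- which(plateau)
    visited[plat_lin] <- TRUE
    if (any(nm[plat_lin] > a[li])) next # plateau touches brighter voxels
    ok <- plat_lin[in_band[plat_lin]]
    if (length(ok) == 0L) next
    idx <- arrayInd(ok, d)
    keep <- rbind(keep, idx[lex_order(idx)[1L], , drop = FALSE])
  }
  if (nrow(keep) == 0L) return(empty_seeds())

  seeds <- data.frame(i = keep[, 1L], j = keep[, 2L], k = keep[, 3L],
                      intensity = a[keep], origin = "automatic")
  o <- order(-seeds$intensity, seeds$i, seeds$j, seeds$k)
  seeds <- seeds[o, , drop = FALSE]
  rownames(seeds) <- NULL
  filter_by_separation(seeds, params$min_separation, image$spacing)
}

#' Greedy separation filtering of seeds
#'
#' Walks the list in order (callers pass it sorted by decreasing
#' intensity, so the brightest wins) and keeps a seed iff its physical
#' distance to every already-kept seed is at least `min_separation`.
#'
#' @param seeds seed data.frame (`i, j, k, intensity, ...`).
#' @param min_separation minimal pairwise distance in micrometres
#'   (0 keeps everything).
#' @param spacing voxel spacing in micrometres.
#' @return the filtered seed data.frame, original order preserved.
#' @export
filter_by_separation <- function(seeds, min_separation, spacing) {
  if (nrow(seeds) <= 1L || min_separation <= 0) return(seeds)
  pos <- voxel_center(as.matrix(seeds[, c("i", "j", "k")]), spacing)
  kept <- logical(nrow(seeds))
  kept[1L] <- TRUE
  for (r in 2:nrow(seeds)) {
    dmin <- min(sqrt(colSums((t(pos[kept, , drop = FALSE]) - pos[r, ])^2)))
    kept[r] <- dmin >= min_separation
  }
  out <- seeds[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Add a manual seed near a 3D position
#'
#' Places a seed on the brightest voxel of the in-plane 5x5 window
#' centred on the given voxel, on that slice (optionally scanning
#' `slice_span` slices either side). Ties go to the lexicographically
#' smallest voxel. Manual seeds are exempt from the intensity, distance
#' and separation criteria.
#'
#' @param image an `image_stack`.
#' @param position voxel index triple `(i, j, k)`, 1-based.
#' @param seeds optional existing seed data.frame to append to.
#' @param window odd in-plane window width in voxels (default 5).
#' @param slice_span how many slices either side of `k` to scan
#'   (default 0: the clicked slice only).
#' @return the seed data.frame with the new row appended.
#' @export
add_seed_at <- function(image, position, seeds = NULL, window = 5L,
                        slice_span = 0L) {
  d <- dim(image$data)
  position <- as.integer(position)
  if (length(position) != 3L || any(position < 1L) || any(position > d)) {
    stop("position is outside the image grid", call. = FALSE)
  }
  r <- (window - 1L) %/% 2L
  ii <- max(1L, position[1L] - r):min(d[1L], position[1L] + r)
  jj <- max(1L, position[2L] - r):min(d[2L], position[2L] + r)
  kk <- max(1L, position[3L] - slice_span):min(d[3L], position[3L] + slice_span)
  g <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  g <- g[lex_order(g), , drop = FALSE]
  vals <- image$data[g]
  best <- g[which.max(vals), ] # first max in lexicographic order
  row <- data.frame(i = best[1L], j = best[2L], k = best[3L],
                    intensity = image$data[matrix(best, 1L)],
                    origin = "manual")
  out <- rbind(if (is.null(seeds)) empty_seeds() else seeds, row)
  rownames(out) <- NULL
  out
}

#' Remove the seed nearest a 3D position
#'
#' Deletes exactly one seed: the one whose voxel centre is physically
#' nearest the given position (nearest-neighbour deletion; ties broken
#' lexicographically on the seed voxel).
#'
#' @param seeds non-empty seed data.frame.
#' @param position voxel index triple `(i, j, k)`.
#' @param spacing voxel spacing in micrometres.
#' @return the seed data.frame with one row removed.
#' @export
remove_nearest_seed <- function(seeds, position, spacing) {
  if (is.null(seeds) || nrow(seeds) == 0L) {
    stop("seed list is empty", call. = FALSE)
  }
  p <- voxel_center(as.integer(position), spacing)
  pos <- voxel_center(as.matrix(seeds[, c("i", "j", "k")]), spacing)
  dist <- sqrt(colSums((t(pos) - as.numeric(p))^2))
  hit <- which(dist == min(dist))
  if (length(hit) > 1L) {
    idx <- as.matrix(seeds[hit, c("i", "j", "k")])
    hit <- hit[lex_order(idx)[1L]]
  }
  out <- seeds[-hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
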