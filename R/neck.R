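# Spine-neck tracing: a one-voxel-wide minimum-cost path from the spine
# head border to the dendrite border, preferring bright voxels. The path
# runs over 26-connected steps weighted by physical step length times a
# brightness penalty, searched on a local corridor around the endpoints.

mask_from_voxels <- function(vox, d) {
  m <- array(FALSE, d)
  m[vox] <- TRUE
  m
}

#' Closest head-border / dendrite-border voxel pair
#'
#' The pair of border voxels (one on the head surface, one on the
#' dendrite surface) minimizing the anisotropic physical distance
#' between voxel centres; these are the endpoints for neck tracing.
#' Ties are broken lexicographically on the head voxel, then the
#' dendrite voxel.
#'
#' @param head head voxels: an n x 3 index matrix (see [head_voxels()])
#'   or a logical mask on the grid.
#' @param volume a `dendrite_volume`.
#' @param spacing voxel spacing in micrometres.
#' @return list with `head_voxel`, `dendrite_voxel` (index triples) and
#'   `distance` in micrometres.
#' @export
closest_border_pair <- function(head, volume, spacing) {
  d <- dim(volume$mask)
  hmask <- if (is.logical(head)) head else mask_from_voxels(head, d)
  if (!any(hmask)) stop("head is empty", call. = FALSE)
  if (!any(volume$mask)) stop("dendrite mask is empty", call. = FALSE)
  hb <- arrayInd(which(border_mask(hmask)), d)
  db_all <- arrayInd(which(volume$border), d)
  # restrict the dendrite border to a padded box around the head
  pad <- ceiling(3 / spacing)
  lo <- pmax(apply(hb, 2L, min) - pad, 1L)
  hi <- pmin(apply(hb, 2L, max) + pad, d)
  inbox <- db_all[, 1L] >= lo[1L] & db_all[, 1L] <= hi[1L] &
    db_all[, 2L] >= lo[2L] & db_all[, 2L] <= hi[2L] &
    db_all[, 3L] >= lo[3L] & db_all[, 3L] <= hi[3L]
  db <- if (any(inbox)) db_all[inbox, , drop = FALSE] else db_all
  dm <- voxel_distances(hb, db, spacing)
  best <- min(dm)
  hits <- which(dm == best, arr.ind = TRUE)
  o <- order(hb[hits[, 1L], 1L], hb[hits[, 1L], 2L], hb[hits[, 1L], 3L],
             db[hits[, 2L], 1L], db[hits[, 2L], 2L], db[hits[, 2L], 3L])
  hit <- hits[o[1L], ]
  list(head_voxel = hb[hit[1L], ], dendrite_voxel = db[hit[2L], ],
       distance = best)
}

neck_path <- function(voxels, length_um, mode, start = NULL, end = NULL) {
  structure(list(voxels = voxels, length = length_um, mode = mode,
                 start = start, end = end),
            class = "neck_path")
}

#' @export
print.neck_path <- function(x, ...) {
  cat(sprintf("neck_path (%s): %d voxels, length %.3f um\n", x$mode,
              if (is.null(x$voxels)) 0L else nrow(x$voxels), x$length))
  invisible(x)
}

path_step_lengths <- function(vox, spacing) {
  if (nrow(vox) < 2L) return(numeric())
  steps <- diff(vox)
  sqrt((steps[, 1L] * spacing[1L])^2 + (steps[, 2L] * spacing[2L])^2 +
         (steps[, 3L] * spacing[3L])^2)
}

#' Trace a spine neck as a minimum-cost bright path
#'
#' Finds the minimum-cost 26-connected path from the head-border voxel to
#' the dendrite-border voxel. Each step costs its physical length times
#' the mean brightness weight `1 + (I_max - I) / (I_max - I_min)` of its
#' two voxels (`I_max`/`I_min` over the search corridor), so the search
#' follows bright neck signal instead of cutting dark corners. The
#' corridor is the bounding box of the two endpoints padded by
#' `corridor_pad` micrometres; head-interior and dendrite voxels are
#' barred (except the two endpoints). Per the neck definition the final
#' dendrite-border voxel is dropped: the returned path runs from the head
#' edge to the voxel preceding the dendrite border, and its length is the
#' sum of the physical step lengths along it. If no path exists inside
#' the corridor the neck falls back to `straight_line` mode (endpoint
#' distance) with a warning.
#'
#' @param image an `image_stack`.
#' @param head_voxel,dendrite_voxel endpoint voxel index triples, e.g.
#'   from [closest_border_pair()].
#' @param head_mask,dendrite_mask logical arrays of head and dendrite
#'   voxels.
#' @param corridor_pad corridor padding in micrometres (default 1).
#' @return a `neck_path`.
#' @export
trace_neck <- function(image, head_voxel, dendrite_voxel, head_mask,
                       dendrite_mask, corridor_pad = 1) {
  d <- dim(image$data)
  if (d[3L] == 1L) {
    stop("neck tracing requires a 3D stack", call. = FALSE)
  }
  spacing <- image$spacing
  head_voxel <- as.integer(head_voxel)
  dendrite_voxel <- as.integer(dendrite_voxel)
  pad <- ceiling(corridor_pad / spacing)
  lo <- pmax(pmin(head_voxel, dendrite_voxel) - pad, 1L)
  hi <- pmin(pmax(head_voxel, dendrite_voxel) + pad, d)
  ii <- lo[1L]:hi[1L]; jj <- lo[2L]:hi[2L]; kk <- lo[3L]:hi[3L]
  sd3 <- c(length(ii), length(jj), length(kk))

  sub <- image$data[ii, jj, kk, drop = FALSE];  dim(sub) <- sd3
  hm <- head_mask[ii, jj, kk];                  dim(hm) <- sd3
  dm <- dendrite_mask[ii, jj, kk];              dim(dm) <- sd3
  s_loc <- head_voxel - lo + 1L
  e_loc <- dendrite_voxel - lo + 1L
  allowed <- !(hm | dm)
  allowed[matrix(s_loc, 1L)] <- TRUE
  allowed[matrix(e_loc, 1L)] <- TRUE

  rng <- range(sub)
  w <- if (diff(rng) > 0) 1 + (rng[2L] - sub) / (rng[2L] - rng[1L]) else
    array(1, sd3)

  lin <- function(ix) ix[, 1L] + sd3[1L] * (ix[, 2L] - 1L + sd3[2L] * (ix[, 3L] - 1L))
  allowed_lin <- which(allowed)
  node_of <- integer(prod(sd3))
  node_of[allowed_lin] <- seq_along(allowed_lin)
  vox_all <- arrayInd(allowed_lin, sd3)

  offs <- neighbor_offsets(26L)
  offs <- offs[offs[, 1L] > 0L | (offs[, 1L] == 0L & offs[, 2L] > 0L) |
                 (offs[, 1L] == 0L & offs[, 2L] == 0L & offs[, 3L] > 0L), ,
               drop = FALSE] # half the offsets: undirected edges once
  from <- integer(); to <- integer(); wt <- numeric()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- sweep(vox_all, 2L, off, "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= sd3[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= sd3[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= sd3[3L]
    nb_lin <- lin(nb[ok, , drop = FALSE])
    src <- which(ok)[allowed[nb_lin]]
    dst <- node_of[nb_lin[allowed[nb_lin]]]
    step <- sqrt(sum((off * spacing)^2))
    from <- c(from, src)
    to <- c(to, dst)
    wt <- c(wt, step * (w[allowed_lin[src]] + w[allowed_lin[dst]]) / 2)
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)),
                          n = length(allowed_lin), directed = FALSE)
  s_node <- node_of[lin(matrix(s_loc, 1L))]
  e_node <- node_of[lin(matrix(e_loc, 1L))]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = s_node, to = e_node, weights = wt,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1L]])
  if (length(vp) == 0L ||
      (length(vp) == 1L && !identical(s_node, e_node))) {
    warning("no path between head and dendrite inside the corridor; ",
            "falling back to straight-line length", call. = FALSE)
    len <- sqrt(sum(((head_voxel - dendrite_voxel) * spacing)^2))
    return(neck_path(NULL, len, "straight_line", head_voxel, dendrite_voxel))
  }
  vox <- sweep(vox_all[vp, , drop = FALSE], 2L, lo - 1L, "+")
  vox <- vox[-nrow(vox), , drop = FALSE] # drop the dendrite-border voxel
  storage.mode(vox) <- "integer"
  neck_path(vox, sum(path_step_lengths(vox, spacing)), "traced",
            head_voxel, dendrite_voxel)
}

#' Straight-line spine length
#'
#' For stacks in which necks are not resolvable: the Euclidean distance
#' from the head centroid to the nearest dendrite-surface voxel centre,
#' an estimate of spine length.
#'
#' @inheritParams closest_border_pair
#' @return length in micrometres.
#' @export
straight_line_length <- function(head, volume, spacing) {
  d <- dim(volume$mask)
  vox <- if (is.logical(head)) arrayInd(which(head), d) else head
  if (nrow(vox) == 0L) stop("head is empty", call. = FALSE)
  centroid <- colMeans(voxel_center(vox, spacing))
  db <- voxel_center(arrayInd(which(volume$border), d), spacing)
  min(sqrt((db[, 1L] - centroid[1L])^2 + (db[, 2L] - centroid[2L])^2 +
             (db[, 3L] - centroid[3L])^2))
}

#' Classify a spine as stubby or necked
#'
#' A spine is stubby iff its head is in contact with the dendrite: some
#' head voxel is a neighbour (26-connected by default; set
#' `connectivity = 6` for a stricter face-contact test) of a dendrite
#' mask voxel. Stubby spines get neck length 0 and no traced neck.
#'
#' @inheritParams closest_border_pair
#' @param connectivity 26 (default) or 6.
#' @return `"stubby"` or `"necked"`.
#' @export
classify_stubby <- function(head, volume, connectivity = 26L) {
  d <- dim(volume$mask)
  hmask <- if (is.logical(head)) head else mask_from_voxels(head, d)
  if (!any(hmask)) stop("head is empty", call. = FALSE)
  touching <- any(binary_dilate(volume$mask,
                                neighbor_offsets(connectivity)) & hmask)
  if (touching) "stubby" else "necked"
}

#' Re-trace a neck from a new starting point
#'
#' The dendrite endpoint is recomputed as the dendrite-border voxel
#' nearest the imposed start, and the path re-traced.
#'
#' @param image an `image_stack`.
#' @param head head voxels (matrix or logical mask).
#' @param new_start_voxel voxel index triple on the head border.
#' @param volume a `dendrite_volume`.
#' @param corridor_pad corridor padding in micrometres.
#' @return a `neck_path`.
#' @export
retrace_neck <- function(image, head, new_start_voxel, volume,
                         corridor_pad = 1) {
  d <- dim(volume$mask)
  hmask <- if (is.logical(head)) head else mask_from_voxels(head, d)
  hb <- border_mask(hmask)
  new_start_voxel <- as.integer(new_start_voxel)
  if (!hb[matrix(new_start_voxel, 1L)]) {
    stop("new start voxel is not on the head border", call. = FALSE)
  }
  db <- arrayInd(which(volume$border), d)
  dist <- voxel_distances(matrix(new_start_voxel, 1L), db, image$spacing)
  hit <- which(dist == min(dist))
  if (length(hit) > 1L) hit <- hit[lex_order(db[hit, , drop = FALSE])[1L]]
  trace_neck(image, new_start_voxel, db[hit, ], hmask, volume$mask,
             corridor_pad)
}

#' Trace all spine necks
#'
#' Per head, in label order: stubby heads (see [classify_stubby()]) get
#' neck length 0 and no path; otherwise the closest border pair is found
#' and either traced ([trace_neck()]) or, in `straight_line` mode,
#' measured as centroid-to-dendrite distance ([straight_line_length()]).
#' The mode is a global per-run switch.
#'
#' @param image an `image_stack`.
#' @param heads a `spine_heads` object.
#' @param volume a `dendrite_volume`.
#' @param mode `"traced"` (default) or `"straight_line"`.
#' @param corridor_pad corridor padding in micrometres for tracing.
#' @return list with `paths` (named list of `neck_path` or `NULL`, one
#'   per head) and `table` (data.frame `label`, `spine_type`,
#'   `neck_length`, `distance_to_dendrite`, `neck_mode`).
#' @export
trace_all_necks <- function(image, heads, volume,
                            mode = c("traced", "straight_line"),
                            corridor_pad = 1) {
  mode <- match.arg(mode)
  if (mode == "traced" && dim(image$data)[3L] == 1L) {
    stop("neck tracing requires a 3D stack; use mode = \"straight_line\" ",
         "or provide a 3D image", call. = FALSE)
  }
  labs <- sort(heads$info$label)
  paths <- setNames(vector("list", length(labs)), as.character(labs))
  rows <- vector("list", length(labs))
  for (q in seq_along(labs)) {
    lab <- labs[q]
    vox <- head_voxels(heads, lab)
    type <- classify_stubby(vox, volume)
    pair <- closest_border_pair(vox, volume, image$spacing)
    if (type == "stubby") {
      rows[[q]] <- data.frame(label = lab, spine_type = "stubby",
                              neck_length = 0,
                              distance_to_dendrite = pair$distance,
                              neck_mode = "none")
      next
    }
    if (mode == "traced") {
      hmask <- mask_from_voxels(vox, dim(volume$mask))
      np <- trace_neck(image, pair$head_voxel, pair$dendrite_voxel, hmask,
                       volume$mask, corridor_pad)
      paths[[q]] <- np
      rows[[q]] <- data.frame(label = lab, spine_type = "necked",
                              neck_length = np$length,
                              distance_to_dendrite = pair$distance,
                              neck_mode = np$mode)
    } else {
      len <- straight_line_length(vox, volume, image$spacing)
      rows[[q]] <- data.frame(label = lab, spine_type = "necked",
                              neck_length = len,
                              distance_to_dendrite = pair$distance,
                              neck_mode = "straight_line")
    }
  }
  list(paths = paths, table = do.call(rbind, rows))
}
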