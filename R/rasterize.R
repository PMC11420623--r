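# Volumetric realization of an SWC model: a sphere at every node plus a
# conical frustum along every parent-child segment, with the radius
# linearly interpolated by projected arclength. This is the tapered-
# capsule union commonly used to turn a skeleton-with-radii tracing into
# a voxel volume.

#' Rasterize a dendrite model onto a voxel grid
#'
#' A voxel belongs to the dendrite iff its centre lies within the sphere
#' of any SWC node or within the conical frustum joining any parent-child
#' pair (radius linearly interpolated along the segment, projection
#' clamped to the segment ends, which yields spherical end caps at the
#' nodes).
#'
#' @param model a `dendrite_model` from [parse_swc()].
#' @param spacing voxel spacing `(dx, dy, dz)` in micrometres.
#' @param grid_shape integer dimensions of the target grid; when `NULL`
#'   the grid covers the model's bounding box padded by the maximum
#'   radius plus one voxel.
#' @param origin physical coordinate of the grid corner (the centre of
#'   voxel `(1,1,1)` sits at `origin + spacing/2`); defaults to `(0,0,0)`
#'   when `grid_shape` is given, or to the padded bounding-box corner.
#' @return A `dendrite_volume`: list with `mask` (3D logical), `spacing`,
#'   `origin`, and `border` (logical array of inside voxels having a
#'   6-connected outside neighbour; the grid edge counts as outside).
#' @export
rasterize_dendrite <- function(model, spacing, grid_shape = NULL,
                               origin = NULL) {
  stopifnot(inherits(model, "dendrite_model"))
  spacing <- check_spacing(spacing)
  n <- model$nodes
  if (nrow(n) == 0L) stop("cannot rasterize an empty model", call. = FALSE)
  if (is.null(grid_shape)) {
    pad <- max(n$radius) + max(spacing)
    if (is.null(origin)) {
      origin <- c(min(n$x), min(n$y), min(n$z)) - pad
    }
    hi <- c(max(n$x), max(n$y), max(n$z)) + pad
    grid_shape <- pmax(1L, as.integer(ceiling((hi - origin) / spacing)))
  } else if (is.null(origin)) {
    origin <- c(0, 0, 0)
  }
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))

  mask <- array(FALSE, grid_shape)
  # axis coordinate vectors of voxel centres, per dimension
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(grid_shape[a]) - 0.5) * spacing[a])

  # index range of voxels whose centres may fall inside [lo, hi]
  rng <- function(a, lo, hi) {
    i1 <- max(1L, as.integer(floor((lo - origin[a]) / spacing[a] + 0.5)))
    i2 <- min(grid_shape[a], as.integer(ceiling((hi - origin[a]) / spacing[a] + 0.5)))
    if (i1 > i2) integer() else i1:i2
  }

  paint_segment <- function(p1, r1, p2, r2) {
    rmax <- max(r1, r2)
    ii <- rng(1L, min(p1[1], p2[1]) - rmax, max(p1[1], p2[1]) + rmax)
    jj <- rng(2L, min(p1[2], p2[2]) - rmax, max(p1[2], p2[2]) + rmax)
    kk <- rng(3L, min(p1[3], p2[3]) - rmax, max(p1[3], p2[3]) + rmax)
    if (!length(ii) || !length(jj) || !length(kk)) return(invisible())
    g <- expand.grid(x = ax[[1L]][ii], y = ax[[2L]][jj], z = ax[[3L]][kk])
    u <- p2 - p1
    L2 <- sum(u^2)
    if (L2 == 0) {
      d2 <- (g$x - p1[1])^2 + (g$y - p1[2])^2 + (g$z - p1[3])^2
      inside <- d2 <= rmax^2
    } else {
      t <- ((g$x - p1[1]) * u[1] + (g$y - p1[2]) * u[2] +
              (g$z - p1[3]) * u[3]) / L2
      t <- pmin(pmax(t, 0), 1)
      cx <- p1[1] + t * u[1]
      cy <- p1[2] + t * u[2]
      cz <- p1[3] + t * u[3]
      d2 <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2
      r <- r1 + t * (r2 - r1)
      inside <- d2 <= r^2
    }
    if (any(inside)) {
      sub <- array(inside, c(length(ii), length(jj), length(kk)))
      cur <- mask[ii, jj, kk]
      dim(cur) <- dim(sub)
      mask[ii, jj, kk] <<- cur | sub
    }
    invisible()
  }

  for (r in seq_len(nrow(n))) {
    p <- c(n$x[r], n$y[r], n$z[r])
    paint_segment(p, n$radius[r], p, n$radius[r])
  }
  e <- model$edges
  for (r in seq_len(nrow(e))) {
    paint_segment(c(n$x[e[r, 1L]], n$y[e[r, 1L]], n$z[e[r, 1L]]),
                  n$radius[e[r, 1L]],
                  c(n$x[e[r, 2L]], n$y[e[r, 2L]], n$z[e[r, 2L]]),
                  n$radius[e[r, 2L]])
  }

  structure(list(mask = mask, spacing = spacing, origin = as.numeric(origin),
                 border = border_mask(mask)),
            class = "dendrite_volume")
}

#' Distance-from-dendrite-border map
#'
#' For every voxel, the Euclidean distance in micrometres (between voxel
#' centres, honouring anisotropic spacing) to the nearest dendrite border
#' voxel. Border voxels themselves map to 0; voxels interior to the
#' dendrite are also set to 0, since the spine search band only concerns
#' the outside. This is the field against which the detection distance
#' band (`dist_min`, `dist_max`) is evaluated.
#'
#' @param volume a `dendrite_volume` from [rasterize_dendrite()].
#' @return 3D numeric array of distances in micrometres.
#' @export
border_distance_map <- function(volume) {
  stopifnot(inherits(volume, "dendrite_volume"))
  if (!any(volume$mask)) {
    stop("dendrite mask is empty; cannot compute a border distance map",
         call. = FALSE)
  }
  d <- dim(volume$mask)
  dist <- array(.edt3d(as.logical(volume$border), d, volume$spacing), d)
  dist[volume$mask] <- 0
  dist
}

#' @export
print.dendrite_volume <- function(x, ...) {
  cat(sprintf(
    "dendrite_volume: %s grid, spacing (%s) um, %d inside voxels\n",
    paste(dim(x$mask), collapse = "x"),
    paste(format(x$spacing), collapse = ", "), sum(x$mask)))
  invisible(x)
}
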