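# Shared voxel-grid helpers. All physical quantities are micrometres;
# arrays are [i, j, k] with spacing (dx, dy, dz) and voxel centres at
# (i - 0.5) * spacing.

check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("spacing must be three positive finite numbers (dx, dy, dz) in um",
         call. = FALSE)
  }
  as.numeric(spacing)
}

#' Physical centre coordinates of voxels
#'
#' @param idx integer matrix with one voxel index triple `(i, j, k)` per row
#'   (a single triple may be given as a vector).
#' @param spacing voxel spacing `(dx, dy, dz)` in micrometres.
#' @return numeric matrix of physical coordinates in micrometres.
#' @export
voxel_center <- function(idx, spacing) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  sweep(idx - 0.5, 2L, spacing, "*")
}

#' Voxel index containing a physical position
#'
#' The voxel with 1-based index `i` spans `[(i-1)*dx, i*dx)`, so a position
#' `p` maps to `floor(p / spacing) + 1`, clamped to the grid.
#'
#' @param pos numeric position(s) in micrometres, one per row.
#' @param spacing voxel spacing in micrometres.
#' @param dims grid dimensions, used to clamp.
#' @return integer matrix of voxel indices.
#' @export
position_to_voxel <- function(pos, spacing, dims) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  idx <- floor(sweep(pos, 2L, spacing, "/")) + 1
  idx <- pmin(pmax(idx, 1), matrix(dims, nrow(idx), 3L, byrow = TRUE))
  storage.mode(idx) <- "integer"
  idx
}

# 6- or 26-connected neighbour offsets as an n x 3 integer matrix
neighbor_offsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    off <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                 c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  } else if (connectivity == 26L) {
    off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
    storage.mode(off) <- "integer"
  } else {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  dimnames(off) <- NULL
  off
}

# Shift a 3D array by (di, dj, dk), padding vacated voxels with `fill`.
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  if (any(abs(off) >= d)) return(out) # shifted entirely off-grid
  src_i <- max(1L, 1L - off[1L]):min(d[1L], d[1L] - off[1L])
  src_j <- max(1L, 1L - off[2L]):min(d[2L], d[2L] - off[2L])
  src_k <- max(1L, 1L - off[3L]):min(d[3L], d[3L] - off[3L])
  out[src_i + off[1L], src_j + off[2L], src_k + off[3L]] <-
    a[src_i, src_j, src_k]
  out
}

# Maximum over the 26-neighbourhood (excluding the voxel itself),
# out-of-grid treated as -Inf.
neighborhood_max <- function(a) {
  offs <- neighbor_offsets(26L)
  out <- array(-Inf, dim(a))
  for (r in seq_len(nrow(offs))) {
    out <- pmax(out, shift_array(a, offs[r, ], -Inf))
  }
  out
}

# Binary dilation of `mask` by the given offsets (out-of-grid = FALSE).
binary_dilate <- function(mask, offsets) {
  out <- mask
  for (r in seq_len(nrow(offsets))) {
    out <- out | shift_array(mask, offsets[r, ], FALSE)
  }
  out
}

# Voxels of `mask` with at least one 6-connected neighbour outside the
# mask; the grid boundary counts as outside.
border_mask <- function(mask) {
  offs <- neighbor_offsets(6L)
  inside_all <- array(TRUE, dim(mask))
  for (r in seq_len(nrow(offs))) {
    inside_all <- inside_all & shift_array(mask, offs[r, ], FALSE)
  }
  mask & !inside_all
}

# Connected component of `allowed` containing seed voxels, by iterated
# frontier expansion. `seeds` is an n x 3 index matrix.
flood_fill <- function(allowed, seeds, connectivity = 26L) {
  d <- dim(allowed)
  offs <- neighbor_offsets(connectivity)
  visited <- array(FALSE, d)
  lin <- function(ix) ix[, 1L] + d[1L] * (ix[, 2L] - 1L + d[2L] * (ix[, 3L] - 1L))
  seeds <- seeds[allowed[lin(seeds)], , drop = FALSE]
  if (nrow(seeds) == 0L) return(visited)
  visited[lin(seeds)] <- TRUE
  frontier <- seeds
  while (nrow(frontier) > 0L) {
    n <- nrow(frontier)
    cand <- frontier[rep(seq_len(n), times = nrow(offs)), , drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), each = n), , drop = FALSE]
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
      cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
      cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    li <- lin(cand)
    keep <- allowed[li] & !visited[li]
    li <- li[keep]
    if (length(li) == 0L) break
    dup <- !duplicated(li)
    li <- li[dup]
    visited[li] <- TRUE
    frontier <- cand[keep, , drop = FALSE][dup, , drop = FALSE]
  }
  visited
}

# Separable anisotropic Gaussian blur. Zero-padding with kernel-weight
# renormalisation at the edges, so constant regions stay constant.
gaussian_blur3d <- function(a, sigma_um, spacing) {
  stopifnot(length(sigma_um) %in% c(1L, 3L))
  if (length(sigma_um) == 1L) sigma_um <- rep(sigma_um, 3L)
  d <- dim(a)
  for (ax in 1:3) {
    sig <- sigma_um[ax] / spacing[ax] # sigma in voxels
    if (sig <= 0) next
    r <- max(1L, ceiling(3 * sig))
    kern <- exp(-(seq(-r, r))^2 / (2 * sig^2))
    n <- d[ax]
    conv <- matrix(0, n, n)
    for (s in seq(-r, r)) {
      rows <- seq_len(n)[seq_len(n) + s >= 1 & seq_len(n) + s <= n]
      conv[cbind(rows, rows + s)] <- kern[s + r + 1L]
    }
    conv <- conv / rowSums(conv)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- conv %*% matrix(ap, nrow = n)
    a <- aperm(array(m, dim(ap)), order(perm))
  }
  a
}

# Physical Euclidean distances between rows of two voxel-index matrices.
voxel_distances <- function(idx_a, idx_b, spacing) {
  pa <- voxel_center(idx_a, spacing)
  pb <- voxel_center(idx_b, spacing)
  sqrt(outer(pa[, 1L], pb[, 1L], "-")^2 +
         outer(pa[, 2L], pb[, 2L], "-")^2 +
         outer(pa[, 3L], pb[, 3L], "-")^2)
}

# Evaluate an expression with a private, seeded RNG stream, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Lexicographic order of voxel triples (i, then j, then k).
lex_order <- function(idx) order(idx[, 1L], idx[, 2L], idx[, 3L])
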