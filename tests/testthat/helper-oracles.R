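# Brute-force oracles, independent of the package's implementation
# paths: plain loops and exhaustive scans on small grids.

rand_mask <- function(dims, p = 0.2) {
  array(runif(prod(dims)) < p, dims)
}

# Border voxels by direct 6-neighbour inspection (grid edge = outside).
oracle_border <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    outside <- apply(nb, 1, function(v) {
      any(v < 1) || v[1] > d[1] || v[2] > d[2] || v[3] > d[3] ||
        !mask[v[1], v[2], v[3]]
    })
    out[i, j, k] <- any(outside)
  }
  out
}

# Exhaustive nearest-border-voxel distance, anisotropic, inside = 0.
oracle_border_distance <- function(mask, spacing) {
  d <- dim(mask)
  border <- which(oracle_border(mask), arr.ind = TRUE)
  out <- array(0, d)
  bp <- sweep(border - 0.5, 2, spacing, "*")
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) next
    p <- (c(i, j, k) - 0.5) * spacing
    out[i, j, k] <- sqrt(min((bp[, 1] - p[1])^2 + (bp[, 2] - p[2])^2 +
                               (bp[, 3] - p[3])^2))
  }
  out
}

# Quadratic-scan greedy separation filter.
oracle_separation <- function(seeds, min_sep, spacing) {
  kept <- integer()
  for (r in seq_len(nrow(seeds))) {
    p <- (c(seeds$i[r], seeds$j[r], seeds$k[r]) - 0.5) * spacing
    ok <- TRUE
    for (q in kept) {
      pq <- (c(seeds$i[q], seeds$j[q], seeds$k[q]) - 0.5) * spacing
      if (sqrt(sum((p - pq)^2)) < min_sep) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, r)
  }
  seeds[kept, , drop = FALSE]
}

# Exhaustive nearest-seed scan (lexicographic tie-break).
oracle_nearest_seed <- function(seeds, position, spacing) {
  p <- (position - 0.5) * spacing
  d <- apply(seeds[, c("i", "j", "k")], 1, function(v) {
    sqrt(sum(((v - 0.5) * spacing - p)^2))
  })
  hits <- which(d == min(d))
  hits[order(seeds$i[hits], seeds$j[hits], seeds$k[hits])][1]
}

# Exhaustive closest pair between two border voxel sets.
oracle_closest_pair <- function(head_mask, dend_mask, spacing) {
  hb <- which(oracle_border(head_mask), arr.ind = TRUE)
  db <- which(oracle_border(dend_mask), arr.ind = TRUE)
  best <- Inf; bh <- NULL; bd <- NULL
  for (a in seq_len(nrow(hb))) for (b in seq_len(nrow(db))) {
    dist <- sqrt(sum(((hb[a, ] - db[b, ]) * spacing)^2))
    if (dist < best - 1e-12) {
      best <- dist; bh <- hb[a, ]; bd <- db[b, ]
    }
  }
  list(head_voxel = bh, dendrite_voxel = bd, distance = best)
}

# Plain Dijkstra over a voxel grid with 26-connected steps; cost per
# step = physical length x mean endpoint brightness weight, with the
# weights computed from the global min/max of `img`. Returns the
# minimal total cost from `start` to `end`.
oracle_path_cost <- function(img, spacing, start, end, allowed = NULL) {
  d <- dim(img)
  if (is.null(allowed)) allowed <- array(TRUE, d)
  rng <- range(img)
  w <- if (diff(rng) > 0) 1 + (rng[2] - img) / (rng[2] - rng[1]) else
    array(1, d)
  n <- prod(d)
  lin <- function(v) v[1] + d[1] * (v[2] - 1 + d[2] * (v[3] - 1))
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[lin(start)] <- 0
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) return(Inf)
    if (u == lin(end)) return(dist[u])
    done[u] <- TRUE
    uv <- c((u - 1) %% d[1] + 1,
            ((u - 1) %/% d[1]) %% d[2] + 1,
            (u - 1) %/% (d[1] * d[2]) + 1)
    for (r in seq_len(nrow(offs))) {
      v <- uv + offs[r, ]
      if (any(v < 1) || any(v > d)) next
      if (!allowed[v[1], v[2], v[3]]) next
      lv <- lin(v)
      step <- sqrt(sum((offs[r, ] * spacing)^2))
      cost <- step * (w[u] + w[lv]) / 2
      if (dist[u] + cost < dist[lv]) dist[lv] <- dist[u] + cost
    }
  }
}

# Total cost of a given voxel path under the same cost model.
path_cost <- function(img, spacing, vox) {
  rng <- range(img)
  w <- if (diff(rng) > 0) 1 + (rng[2] - img) / (rng[2] - rng[1]) else
    array(1, dim(img))
  total <- 0
  for (r in seq_len(nrow(vox) - 1)) {
    step <- sqrt(sum(((vox[r + 1, ] - vox[r, ]) * spacing)^2))
    total <- total + step * (w[matrix(vox[r, ], 1)] +
                               w[matrix(vox[r + 1, ], 1)]) / 2
  }
  total
}
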