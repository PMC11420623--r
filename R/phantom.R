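# Synthetic dendrite + spine phantoms with exact ground truth. The
# generator emulates a confocal/two-photon stack of a labelled dendrite:
# binary geometry rendered at chosen intensity levels, blurred with an
# anisotropic Gaussian PSF (broader axially), then Poisson photon noise
# and additive Gaussian readout noise.

#' Specify a synthetic dendrite + spine phantom
#'
#' Defaults mimic a high-resolution confocal acquisition: 64x64x32
#' voxels at (0.06, 0.06, 0.2) um spacing, PSF sigmas (0.08, 0.25) um
#' (lateral, axial), a 0.4 um-radius dendrite running along x through
#' the grid centre, and 8-bit-range intensity levels. Noise defaults to
#' off; set `gaussian_sd` and/or `photons_per_unit` to add readout and
#' photon noise (SNR is conventionally `(head - background) /
#' sigma_background`).
#'
#' @param n_spines number of spines (used when `spines` is `NULL`).
#' @param spines optional data.frame overriding the default layout, with
#'   columns `position` (um along the dendrite axis), `angle` (radians,
#'   azimuth in the y-z plane), `neck_length`, `neck_radius`,
#'   `head_radius` (um) and `type` (`"necked"` or `"stubby"`).
#' @param dims grid dimensions.
#' @param spacing voxel spacing in micrometres.
#' @param dendrite_radius dendrite radius in micrometres.
#' @param psf_sigma PSF sigmas `(lateral, axial)` in micrometres.
#' @param levels named intensities for `background`, `dendrite`, `neck`,
#'   `head`.
#' @param photons_per_unit Poisson scale: expected photons per intensity
#'   unit (0 disables photon noise).
#' @param gaussian_sd additive Gaussian noise sigma, intensity units
#'   (0 disables).
#' @param seed RNG seed used by [render_phantom()] for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(n_spines = 5L, spines = NULL,
                         dims = c(64L, 64L, 32L),
                         spacing = c(0.06, 0.06, 0.2),
                         dendrite_radius = 0.4,
                         psf_sigma = c(0.08, 0.25),
                         levels = c(background = 10, dendrite = 200,
                                    neck = 150, head = 255),
                         photons_per_unit = 0, gaussian_sd = 0,
                         seed = 1L) {
  spacing <- check_spacing(spacing)
  stopifnot(length(dims) == 3L, all(dims >= 4L), dendrite_radius > 0,
            all(psf_sigma > 0), photons_per_unit >= 0, gaussian_sd >= 0)
  extent <- dims * spacing
  if (is.null(spines)) {
    spines <- default_spine_layout(n_spines, extent[1L])
  }
  needed <- c("position", "angle", "neck_length", "neck_radius",
              "head_radius", "type")
  stopifnot(all(needed %in% names(spines)))
  if (any(spines$head_radius <= 0) || any(spines$neck_radius <= 0) ||
        any(spines$neck_length < 0)) {
    stop("spine radii must be positive and neck lengths non-negative",
         call. = FALSE)
  }
  structure(list(dims = as.integer(dims), spacing = spacing,
                 dendrite_radius = dendrite_radius, spines = spines,
                 psf_sigma = psf_sigma, levels = levels,
                 photons_per_unit = photons_per_unit,
                 gaussian_sd = gaussian_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evenly spaced spines along the dendrite, azimuths rotating around the
# shaft so neighbours point in different directions. Geometry chosen to
# resemble mature cortical spines: 0.4 um head radius, 0.5 um neck of
# 0.12 um radius; stubby spines sit directly on the shaft.
default_spine_layout <- function(n, x_extent, types = NULL,
                                 neck_length = 0.5, head_radius = 0.4) {
  stopifnot(n >= 1L)
  margin <- 0.45
  pos <- seq(margin, x_extent - margin, length.out = n)
  types <- types %||% rep("necked", n)
  data.frame(position = pos,
             angle = (seq_len(n) - 1L) * 2 * pi / max(n, 2L) + pi / 5,
             neck_length = ifelse(types == "stubby", 0, neck_length),
             neck_radius = 0.12, head_radius = head_radius, type = types)
}

# Spine geometry in physical coordinates: anchor on the dendrite
# surface, head centre further out along the same radial direction.
spine_geometry <- function(spec) {
  extent <- spec$dims * spec$spacing
  axis_y <- extent[2L] / 2
  axis_z <- extent[3L] / 2
  sp <- spec$spines
  dir_y <- cos(sp$angle)
  dir_z <- sin(sp$angle)
  anchor <- cbind(sp$position, axis_y + spec$dendrite_radius * dir_y,
                  axis_z + spec$dendrite_radius * dir_z)
  reach <- ifelse(sp$type == "stubby", 0.5 * sp$head_radius,
                  sp$neck_length + sp$head_radius)
  center <- cbind(sp$position, axis_y + (spec$dendrite_radius + reach) * dir_y,
                  axis_z + (spec$dendrite_radius + reach) * dir_z)
  list(anchor = anchor, center = center,
       dir = cbind(0, dir_y, dir_z),
       axis = c(axis_y, axis_z))
}

#' Render a phantom stack with ground truth
#'
#' Rasterizes the dendrite through [rasterize_dendrite()] of its own SWC
#' model (so phantom and pipeline share one dendrite realization), adds
#' each spine as a head sphere plus (for necked spines) a neck cylinder
#' from the shaft surface to the head, composites the intensity levels
#' (brightest structure wins), blurs with the anisotropic PSF, and
#' applies seeded Poisson/Gaussian noise. Deterministic given the seed;
#' spines whose capsules intersect raise an error so the ground truth
#' stays unambiguous.
#'
#' @param spec a `phantom_spec`.
#' @return list with `stack` (an `image_stack`), `model` (the dendrite
#'   SWC model), `volume` (its `dendrite_volume` on the phantom grid)
#'   and `truth` (data.frame: `spine_id`, true head centre
#'   `center_x/y/z_um`, `head_radius_um`, `head_volume_um3` (analytic
#'   sphere volume), `neck_length_um`, `type`).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  spacing <- spec$spacing
  extent <- d * spacing
  geo <- spine_geometry(spec)
  sp <- spec$spines
  check_spine_overlap(spec, geo)

  swc_text <- c(
    sprintf("1 0 %g %g %g %g -1", 0.5 * spacing[1L], geo$axis[1L],
            geo$axis[2L], spec$dendrite_radius),
    sprintf("2 0 %g %g %g %g 1", extent[1L] - 0.5 * spacing[1L],
            geo$axis[1L], geo$axis[2L], spec$dendrite_radius))
  model <- parse_swc(swc_text)
  volume <- rasterize_dendrite(model, spacing, grid_shape = d)

  img <- array(spec$levels[["background"]], d)
  img[volume$mask] <- pmax(img[volume$mask], spec$levels[["dendrite"]])

  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * spacing[a])
  paint <- function(test_fn, bbox_lo, bbox_hi, level) {
    ii <- which(ax[[1L]] >= bbox_lo[1L] & ax[[1L]] <= bbox_hi[1L])
    jj <- which(ax[[2L]] >= bbox_lo[2L] & ax[[2L]] <= bbox_hi[2L])
    kk <- which(ax[[3L]] >= bbox_lo[3L] & ax[[3L]] <= bbox_hi[3L])
    if (!length(ii) || !length(jj) || !length(kk)) return(invisible())
    g <- expand.grid(x = ax[[1L]][ii], y = ax[[2L]][jj], z = ax[[3L]][kk])
    inside <- test_fn(g)
    if (any(inside)) {
      sub <- img[ii, jj, kk]
      dim(sub) <- c(length(ii), length(jj), length(kk))
      sub[array(inside, dim(sub))] <- pmax(sub[array(inside, dim(sub))], level)
      img[ii, jj, kk] <<- sub
    }
    invisible()
  }

  for (s in seq_len(nrow(sp))) {
    ctr <- geo$center[s, ]
    r <- sp$head_radius[s]
    paint(function(g) (g$x - ctr[1L])^2 + (g$y - ctr[2L])^2 +
            (g$z - ctr[3L])^2 <= r^2,
          ctr - r, ctr + r, spec$levels[["head"]])
    if (sp$type[s] != "stubby" && sp$neck_length[s] > 0) {
      a <- geo$anchor[s, ]
      b <- ctr
      u <- b - a
      L2 <- sum(u^2)
      rn <- sp$neck_radius[s]
      paint(function(g) {
        t <- ((g$x - a[1L]) * u[1L] + (g$y - a[2L]) * u[2L] +
                (g$z - a[3L]) * u[3L]) / L2
        t <- pmin(pmax(t, 0), 1)
        (g$x - (a[1L] + t * u[1L]))^2 + (g$y - (a[2L] + t * u[2L]))^2 +
          (g$z - (a[3L] + t * u[3L]))^2 <= rn^2
      }, pmin(a, b) - rn, pmax(a, b) + rn, spec$levels[["neck"]])
    }
  }

  img <- gaussian_blur3d(img, c(spec$psf_sigma[1L], spec$psf_sigma[1L],
                                spec$psf_sigma[2L]), spacing)
  img <- with_seed(spec$seed, {
    out <- img
    if (spec$photons_per_unit > 0) {
      out <- rpois(length(out), out * spec$photons_per_unit) /
        spec$photons_per_unit
      dim(out) <- d
    }
    if (spec$gaussian_sd > 0) {
      out <- out + rnorm(length(out), 0, spec$gaussian_sd)
      dim(out) <- d
    }
    out
  })
  img <- pmin(pmax(img, 0), 2^16 - 1)

  truth <- data.frame(
    spine_id = seq_len(nrow(sp)),
    center_x_um = geo$center[, 1L], center_y_um = geo$center[, 2L],
    center_z_um = geo$center[, 3L],
    head_radius_um = sp$head_radius,
    head_volume_um3 = 4 / 3 * pi * sp$head_radius^3,
    neck_length_um = ifelse(sp$type == "stubby", 0, sp$neck_length),
    type = sp$type)

  list(stack = image_stack(img, spacing, bit_depth = 16L), model = model,
       volume = volume, truth = truth)
}

# Pairwise clearance test between spine surfaces. Each spine is the
# union of a head sphere and (for necked spines) a neck capsule;
# touching surfaces would make the ground truth ambiguous, so any pair
# of parts from different spines whose clearance is non-positive is an
# error.
check_spine_overlap <- function(spec, geo) {
  n <- nrow(spec$spines)
  if (n < 2L) return(invisible())
  sp <- spec$spines
  parts_of <- function(s) {
    out <- list(list(a = geo$center[s, ], b = geo$center[s, ],
                     r = sp$head_radius[s]))
    if (sp$type[s] != "stubby" && sp$neck_length[s] > 0) {
      out <- c(out, list(list(a = geo$anchor[s, ], b = geo$center[s, ],
                              r = sp$neck_radius[s])))
    }
    out
  }
  for (a in seq_len(n - 1L)) {
    pa <- parts_of(a)
    for (b in (a + 1L):n) {
      for (qa in pa) for (qb in parts_of(b)) {
        dmin <- segment_segment_distance(qa$a, qa$b, qb$a, qb$b)
        if (dmin <= qa$r + qb$r) {
          stop(sprintf("spines %d and %d overlap; adjust the layout", a, b),
               call. = FALSE)
        }
      }
    }
  }
  invisible()
}

# Minimum distance between two 3D segments (sampled finely; segments are
# sub-micrometre so 200 samples give far better than voxel accuracy).
segment_segment_distance <- function(a1, a2, b1, b2) {
  t <- seq(0, 1, length.out = 200L)
  pa <- cbind(a1[1L] + t * (a2[1L] - a1[1L]), a1[2L] + t * (a2[2L] - a1[2L]),
              a1[3L] + t * (a2[3L] - a1[3L]))
  pb <- cbind(b1[1L] + t * (b2[1L] - b1[1L]), b1[2L] + t * (b2[2L] - b1[2L]),
              b1[3L] + t * (b2[3L] - b1[3L]))
  min(sqrt(outer(pa[, 1L], pb[, 1L], "-")^2 +
             outer(pa[, 2L], pb[, 2L], "-")^2 +
             outer(pa[, 3L], pb[, 3L], "-")^2))
}

#' Score detections against phantom ground truth
#'
#' Greedy one-to-one matching: prediction-truth pairs are matched in
#' order of increasing centroid distance, each side used at most once,
#' pairs beyond `match_radius` discarded. Precision = matches /
#' predictions (reported as 1 with `no_predictions = TRUE` when the
#' prediction set is empty), recall = matches / truths. When the
#' prediction table carries `head_volume_um3` / `neck_length_um`
#' columns, per-matched-pair absolute and relative errors are returned.
#'
#' @param predictions data.frame with predicted centres
#'   `centroid_x_um`, `centroid_y_um`, `centroid_z_um` (e.g. a
#'   [spine_table()]), or an n x 3 matrix of centres.
#' @param truth truth data.frame from [render_phantom()].
#' @param match_radius maximal centre-to-centre distance in micrometres
#'   for a valid match (> 0).
#' @return list with `precision`, `recall`, `n_matched`,
#'   `no_predictions`, and `matches` (data.frame of matched pairs with
#'   distances and, when available, volume / neck-length errors).
#' @export
evaluate_detection <- function(predictions, truth, match_radius = 0.5) {
  stopifnot(match_radius > 0)
  if (is.matrix(predictions)) {
    predictions <- data.frame(centroid_x_um = predictions[, 1L],
                              centroid_y_um = predictions[, 2L],
                              centroid_z_um = predictions[, 3L])
  }
  np <- nrow(predictions)
  nt <- nrow(truth)
  if (np == 0L) {
    return(list(precision = 1, recall = 0, n_matched = 0L,
                no_predictions = TRUE,
                matches = data.frame(pred = integer(), truth = integer(),
                                     distance_um = numeric())))
  }
  dm <- sqrt(outer(predictions$centroid_x_um, truth$center_x_um, "-")^2 +
               outer(predictions$centroid_y_um, truth$center_y_um, "-")^2 +
               outer(predictions$centroid_z_um, truth$center_z_um, "-")^2)
  ord <- order(dm)
  used_p <- logical(np)
  used_t <- logical(nt)
  pairs <- list()
  for (q in ord) {
    if (dm[q] > match_radius) break
    pi_ <- (q - 1L) %% np + 1L
    ti <- (q - 1L) %/% np + 1L
    if (used_p[pi_] || used_t[ti]) next
    used_p[pi_] <- TRUE
    used_t[ti] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(pred = pi_, truth = ti,
                                              distance_um = dm[q])
  }
  matches <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pred = integer(), truth = integer(), distance_um = numeric())
  if (nrow(matches) > 0L && "head_volume_um3" %in% names(predictions)) {
    pv <- predictions$head_volume_um3[matches$pred]
    tv <- truth$head_volume_um3[matches$truth]
    matches$volume_error_um3 <- pv - tv
    matches$volume_rel_error <- (pv - tv) / tv
  }
  if (nrow(matches) > 0L && "neck_length_um" %in% names(predictions) &&
        "neck_length_um" %in% names(truth)) {
    pl <- predictions$neck_length_um[matches$pred]
    tl <- truth$neck_length_um[matches$truth]
    matches$neck_error_um <- pl - tl
  }
  list(precision = nrow(matches) / np, recall = nrow(matches) / nt,
       n_matched = nrow(matches), no_predictions = FALSE, matches = matches)
}
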