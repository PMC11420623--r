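#' Construct a calibrated image stack
#'
#' Thin container for a single-channel 3D intensity grid plus its voxel
#' spacing. Intensities are kept in the acquisition's integer scale
#' (0..255 for 8-bit, 0..65535 for 16-bit); 2D images are carried as
#' single-slice stacks.
#'
#' @param data 3D numeric array of finite, non-negative intensities
#'   (a matrix is promoted to a single-slice stack).
#' @param spacing voxel spacing `(dx, dy, dz)` in micrometres.
#' @param bit_depth nominal bit depth, 8 or 16 (used when writing).
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, spacing, bit_depth = 16L) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("image data must be finite and non-negative", call. = FALSE)
  }
  spacing <- check_spacing(spacing)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16",
                                       call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %s voxels, spacing (%s) um, %d-bit, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              x$bit_depth, min(x$data), max(x$data)))
  invisible(x)
}

# Parse an ImageJ-style TIFF ImageDescription ("ImageJ=...\nspacing=0.2\n
# unit=micron") together with the resolution tags into a spacing triple,
# or NULL if the file carries no usable calibration.
parse_tiff_calibration <- function(description = NULL, x_resolution = NULL,
                                   y_resolution = NULL) {
  dz <- NA_real_
  if (!is.null(description) && nzchar(description)) {
    fields <- strsplit(description, "\n", fixed = TRUE)[[1L]]
    kv <- strsplit(fields, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
    if ("spacing" %in% keys) {
      dz <- suppressWarnings(as.numeric(vals[match("spacing", keys)]))
    }
    unit <- if ("unit" %in% keys) vals[match("unit", keys)] else "micron"
    if (!is.na(dz) && !unit %in% c("micron", "um", "µm", "microns")) {
      dz <- NA_real_
    }
  }
  dx <- if (!is.null(x_resolution) && is.finite(x_resolution) &&
              x_resolution > 0) 1 / x_resolution else NA_real_
  dy <- if (!is.null(y_resolution) && is.finite(y_resolution) &&
              y_resolution > 0) 1 / y_resolution else dx
  if (is.na(dx) || is.na(dz)) return(NULL)
  c(dx, dy, dz)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a single-channel 3D TIFF stack
#'
#' Voxel calibration is resolved in order of preference: ImageJ-style
#' TIFF tags (ImageDescription `spacing=`/`unit=` plus the resolution
#' tags), then a JSON sidecar `<path>.json` as written by
#' [write_stack()], then the `spacing` argument. If none yields a
#' calibration, reading fails: downstream geometry is meaningless
#' without physical units.
#'
#' @param path path to the TIFF file.
#' @param spacing optional spacing override `(dx, dy, dz)` in
#'   micrometres; always wins when supplied.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, spacing = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  first <- slices[[1L]]
  nch <- attr(first, "samples.per.pixel")
  if (is.null(nch)) nch <- if (length(dim(first)) == 3L) dim(first)[3L] else 1L
  if (nch != 1L) {
    stop(sprintf("expected a single-channel stack, found %d channels", nch),
         call. = FALSE)
  }
  bits <- attr(first, "bits.per.sample")
  if (is.null(bits) || !bits %in% c(8L, 16L)) bits <- 16L
  scale <- 2^bits - 1

  d <- c(ncol(first), nrow(first), length(slices))
  data <- array(0, d)
  for (k in seq_along(slices)) data[, , k] <- t(slices[[k]]) * scale
  data <- round(data)

  sp <- spacing
  if (is.null(sp)) {
    sp <- parse_tiff_calibration(attr(first, "description"),
                                 attr(first, "x.resolution"),
                                 attr(first, "y.resolution"))
  }
  if (is.null(sp) && file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!is.null(meta$spacing)) sp <- as.numeric(meta$spacing)
  }
  if (is.null(sp)) {
    stop("no voxel calibration in TIFF tags or sidecar; pass `spacing`",
         call. = FALSE)
  }
  image_stack(data, sp, bit_depth = bits)
}

#' Write an image stack (or plain array) as a TIFF plus JSON sidecar
#'
#' The installed TIFF writer cannot emit calibration tags, so spacing and
#' bit depth are recorded in a JSON sidecar `<path>.json`, which
#' [read_stack()] consumes. Intensities are scaled by `2^bit_depth - 1`.
#'
#' @param stack an `image_stack`, or a numeric/logical 3D array (then
#'   `spacing` must be given; logical arrays are written as 0/255 masks).
#' @param path output TIFF path.
#' @param spacing spacing override when `stack` is a bare array.
#' @param bit_depth bits per sample for the file (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, spacing = NULL, bit_depth = NULL) {
  if (!inherits(stack, "image_stack")) {
    a <- stack
    if (is.logical(a)) a <- a * 255
    stack <- image_stack(a, spacing, bit_depth = bit_depth %||% 8L)
  }
  bits <- bit_depth %||% stack$bit_depth
  scale <- 2^bits - 1
  d <- dim(stack$data)
  slices <- lapply(seq_len(d[3L]), function(k) {
    t(pmin(pmax(stack$data[, , k] / scale, 0), 1))
  })
  tiff::writeTIFF(slices, path, bits.per.sample = bits, reduce = FALSE)
  jsonlite::write_json(list(spacing = stack$spacing, bit_depth = bits,
                            channels = 1L),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the four-layer result overlay
#'
#' Mirrors the classic QC display of spine pipelines: channel 1 the
#' original intensities, channel 2 the rasterized dendrite mask, channel
#' 3 the spine-head label image, channel 4 the neck traces burned in as
#' one-voxel-wide rasters.
#'
#' @param image an `image_stack`.
#' @param volume a `dendrite_volume` on the same grid.
#' @param heads a `spine_heads` object (or `NULL` for none).
#' @param necks list of `neck_path` objects (or `NULL`).
#' @param path optional TIFF output path; each channel is written as a
#'   block of z-slices (channel-major) with the layout recorded in the
#'   sidecar.
#' @return 4D array `(x, y, z, channel)`, invisibly when writing.
#' @export
write_overlay <- function(image, volume, heads = NULL, necks = NULL,
                          path = NULL) {
  d <- dim(image$data)
  if (!identical(dim(volume$mask), d)) {
    stop("dendrite volume grid does not match the image grid", call. = FALSE)
  }
  overlay <- array(0, c(d, 4L))
  overlay[, , , 1L] <- image$data
  overlay[, , , 2L] <- volume$mask * 1
  if (!is.null(heads)) {
    if (!identical(dim(heads$labels), d)) {
      stop("head label grid does not match the image grid", call. = FALSE)
    }
    overlay[, , , 3L] <- heads$labels
  }
  if (!is.null(necks)) {
    ch4 <- array(0, d)
    for (np in necks) {
      if (!is.null(np$voxels) && nrow(np$voxels) > 0L) {
        ch4[np$voxels] <- 1
      }
    }
    overlay[, , , 4L] <- ch4
  }
  if (!is.null(path)) {
    scale <- function(a) if (max(a) > 0) a / max(a) else a
    slices <- list()
    for (ch in 1:4) {
      ch_arr <- overlay[, , , ch, drop = FALSE]
      dim(ch_arr) <- d
      ch_arr <- scale(ch_arr)
      for (k in seq_len(d[3L])) {
        slices[[length(slices) + 1L]] <- t(ch_arr[, , k])
      }
    }
    tiff::writeTIFF(slices, path, bits.per.sample = 16L, reduce = FALSE)
    jsonlite::write_json(list(spacing = image$spacing, channels = 4L,
                              slices = d[3L], order = "channel-major"),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
    return(invisible(overlay))
  }
  overlay
}

#' Maximum-intensity projection along z
#'
#' QC export only: editing in this package is 3D-coordinate-based.
#'
#' @param stack an `image_stack`.
#' @return 2D matrix of per-(x, y) maxima.
#' @export
max_projection <- function(stack) {
  apply(stack$data, c(1L, 2L), max)
}
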