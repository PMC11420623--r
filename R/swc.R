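#' Parse an SWC dendrite reconstruction
#'
#' SWC is the plain-text neuron-morphology interchange format: one node per
#' line with columns `id type x y z radius parent`, `#` starting comment
#' lines, and `parent = -1` marking a root. Coordinates and radii are taken
#' as micrometres (the de-facto standard); a `unit_scale` multiplier is
#' applied to x, y, z and radius for files calibrated otherwise.
#'
#' @param text character vector of SWC lines, or a single string with
#'   embedded newlines.
#' @param unit_scale multiplier applied to coordinates and radii
#'   (default 1, i.e. the file is already in micrometres).
#' @return A `dendrite_model`: list with `nodes` (data.frame `id`, `type`,
#'   `x`, `y`, `z`, `radius`, `parent`) and `edges` (two-column integer
#'   matrix of parent/child row indices into `nodes`).
#' @seealso [read_swc()], [write_swc()], [dendrite_length()]
#' @export
parse_swc <- function(text, unit_scale = 1) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lineno <- seq_along(text)
  keep <- !grepl("^\\s*(#|$)", text)
  text <- text[keep]
  lineno <- lineno[keep]

  nodes <- data.frame(id = integer(), type = integer(), x = numeric(),
                      y = numeric(), z = numeric(), radius = numeric(),
                      parent = integer())
  if (length(text) > 0L) {
    fields <- strsplit(trimws(text), "\\s+")
    nf <- lengths(fields)
    if (any(nf != 7L)) {
      bad <- which(nf != 7L)[1L]
      stop(sprintf("SWC line %d: expected 7 columns, found %d",
                   lineno[bad], nf[bad]), call. = FALSE)
    }
    m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7L,
                                 byrow = TRUE))
    if (anyNA(m)) {
      bad <- which(apply(m, 1L, anyNA))[1L]
      stop(sprintf("SWC line %d: non-numeric field", lineno[bad]),
           call. = FALSE)
    }
    nodes <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                        x = m[, 3L] * unit_scale, y = m[, 4L] * unit_scale,
                        z = m[, 5L] * unit_scale,
                        radius = m[, 6L] * unit_scale,
                        parent = as.integer(m[, 7L]))
    if (anyDuplicated(nodes$id)) {
      bad <- which(duplicated(nodes$id))[1L]
      stop(sprintf("SWC line %d: duplicate node id %d", lineno[bad],
                   nodes$id[bad]), call. = FALSE)
    }
    if (any(nodes$radius <= 0)) {
      bad <- which(nodes$radius <= 0)[1L]
      stop(sprintf("SWC line %d: non-positive radius", lineno[bad]),
           call. = FALSE)
    }
    dangling <- nodes$parent != -1L & !(nodes$parent %in% nodes$id)
    if (any(dangling)) {
      bad <- which(dangling)[1L]
      stop(sprintf("SWC line %d: parent id %d does not exist", lineno[bad],
                   nodes$parent[bad]), call. = FALSE)
    }
  }
  child <- which(nodes$parent != -1L)
  edges <- cbind(parent = match(nodes$parent[child], nodes$id), child = child)
  storage.mode(edges) <- "integer"
  structure(list(nodes = nodes, edges = edges), class = "dendrite_model")
}

#' Read an SWC file
#'
#' @param path path to a 7-column SWC file.
#' @inheritParams parse_swc
#' @return a `dendrite_model`; see [parse_swc()].
#' @export
read_swc <- function(path, unit_scale = 1) {
  parse_swc(readLines(path, warn = FALSE), unit_scale = unit_scale)
}

#' Write a dendrite model to SWC
#'
#' Inverse of [parse_swc()]: writing then re-parsing reproduces the node
#' table exactly (numbers are formatted at full precision).
#'
#' @param model a `dendrite_model`.
#' @param path output file path.
#' @export
write_swc <- function(model, path) {
  stopifnot(inherits(model, "dendrite_model"))
  n <- model$nodes
  lines <- c("# SWC written by spinemorph",
             sprintf("%d %d %s %s %s %s %d", n$id, n$type,
                     format(n$x, digits = 17, trim = TRUE, scientific = FALSE),
                     format(n$y, digits = 17, trim = TRUE, scientific = FALSE),
                     format(n$z, digits = 17, trim = TRUE, scientific = FALSE),
                     format(n$radius, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     n$parent))
  writeLines(lines, path)
  invisible(path)
}

#' Total dendrite length
#'
#' Sum of Euclidean parent-child segment lengths over all edges (branched
#' reconstructions simply sum over every edge).
#'
#' @param model a `dendrite_model`.
#' @return length in micrometres (0 for an empty or single-node model).
#' @export
dendrite_length <- function(model) {
  stopifnot(inherits(model, "dendrite_model"))
  e <- model$edges
  if (nrow(e) == 0L) return(0)
  n <- model$nodes
  sum(sqrt((n$x[e[, 1L]] - n$x[e[, 2L]])^2 +
             (n$y[e[, 1L]] - n$y[e[, 2L]])^2 +
             (n$z[e[, 1L]] - n$z[e[, 2L]])^2))
}

#' @export
print.dendrite_model <- function(x, ...) {
  cat(sprintf("dendrite_model: %d nodes, %d edges, length %.3f um\n",
              nrow(x$nodes), nrow(x$edges), dendrite_length(x)))
  invisible(x)
}
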