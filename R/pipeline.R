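# End-to-end pipeline: stack + SWC in, spine table and QC volumes out,
# with a replayable edit script standing in for interactive corrections.

empty_heads <- function(d, spacing) {
  structure(list(labels = array(0L, d),
                 info = data.frame(label = integer(), seed_i = integer(),
                                   seed_j = integer(), seed_k = integer(),
                                   seed_intensity = numeric(),
                                   provenance = character(),
                                   truncated = logical(), note = character(),
                                   n_voxels = integer(),
                                   merged_from = character()),
                 spacing = spacing),
            class = "spine_heads")
}

#' Parse an edit script
#'
#' One command per line (blank lines and `#` comments ignored):
#' \preformatted{
#' add_seed i j k      # manual seed at voxel (i, j, k)
#' remove_seed i j k   # delete the seed nearest voxel (i, j, k)
#' merge a b           # merge head b into head a
#' remove_head L       # delete head L
#' retrace L i j k     # re-trace neck of head L from border voxel (i,j,k)
#' }
#'
#' @param lines character vector of script lines (or a file path).
#' @return data.frame with `line`, `cmd` and integer argument columns.
#' @export
parse_edit_script <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  spec <- c(add_seed = 3L, remove_seed = 3L, merge = 2L, remove_head = 1L,
            retrace = 4L)
  out <- list()
  for (ln in seq_along(lines)) {
    txt <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(txt))) next
    parts <- strsplit(trimws(txt), "\\s+")[[1L]]
    cmd <- parts[1L]
    if (!cmd %in% names(spec)) {
      stop(sprintf("edit script line %d: unknown command '%s'", ln, cmd),
           call. = FALSE)
    }
    args <- suppressWarnings(as.integer(parts[-1L]))
    if (length(args) != spec[[cmd]] || anyNA(args)) {
      stop(sprintf("edit script line %d: '%s' needs %d integer arguments",
                   ln, cmd, spec[[cmd]]), call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      line = ln, cmd = cmd, a1 = args[1L],
      a2 = if (length(args) >= 2L) args[2L] else NA_integer_,
      a3 = if (length(args) >= 3L) args[3L] else NA_integer_,
      a4 = if (length(args) >= 4L) args[4L] else NA_integer_)
  }
  if (length(out) == 0L) {
    return(data.frame(line = integer(), cmd = character(), a1 = integer(),
                      a2 = integer(), a3 = integer(), a4 = integer()))
  }
  do.call(rbind, out)
}

#' Apply edit commands to a pipeline state
#'
#' Replays coordinate-based edits through the stage operations:
#' seed edits via [add_seed_at()] / [remove_nearest_seed()], head edits
#' via [merge_heads()] / [remove_head()], neck edits via
#' [retrace_neck()]. Each command requires its stage output to be
#' present in the state. A log entry is appended per command.
#'
#' @param state list with (as available) `stack`, `volume`, `seeds`,
#'   `heads`, `necks`, `neck_params` and a character `log`.
#' @param script edit script lines, path, or pre-parsed data.frame from
#'   [parse_edit_script()].
#' @return the updated state.
#' @export
apply_edit_script <- function(state, script) {
  cmds <- if (is.data.frame(script)) script else parse_edit_script(script)
  for (r in seq_len(nrow(cmds))) {
    cmd <- cmds$cmd[r]
    args <- c(cmds$a1[r], cmds$a2[r], cmds$a3[r], cmds$a4[r])
    state <- switch(
      cmd,
      add_seed = {
        state$seeds <- add_seed_at(state$stack, args[1:3], state$seeds)
        state
      },
      remove_seed = {
        state$seeds <- remove_nearest_seed(state$seeds, args[1:3],
                                           state$stack$spacing)
        state
      },
      merge = {
        if (is.null(state$heads)) stop("merge before segmentation",
                                       call. = FALSE)
        state$heads <- merge_heads(state$heads, args[1L], args[2L])
        state
      },
      remove_head = {
        if (is.null(state$heads)) stop("remove_head before segmentation",
                                       call. = FALSE)
        state$heads <- remove_head(state$heads, args[1L])
        state
      },
      retrace = {
        if (is.null(state$necks)) stop("retrace before neck tracing",
                                       call. = FALSE)
        lab <- args[1L]
        np <- retrace_neck(state$stack, head_voxels(state$heads, lab),
                           args[2:4], state$volume)
        state$necks$paths[[as.character(lab)]] <- np
        row <- state$necks$table$label == lab
        state$necks$table$neck_length[row] <- np$length
        state$necks$table$neck_mode[row] <- np$mode
        state
      })
    state$log <- c(state$log,
                   sprintf("edit: %s %s", cmd,
                           paste(args[!is.na(args)], collapse = " ")))
  }
  state
}

#' Read a flat key=value run configuration file
#'
#' Recognized keys mirror the [run_pipeline()] config entries, e.g.
#' `stack`, `swc`, `out_dir`, `spacing=dx,dy,dz`, `intensity_min`,
#' `dist_min`, `dist_max`, `min_separation`, `smoothing_sigma`,
#' `threshold_fraction`, `radius_max`, `connectivity`,
#' `background_quantile`, `neck_mode`, `edit_script`, `unit_scale`.
#'
#' @param path path to the config file; `#` comments allowed.
#' @return named list of raw string values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) {
    stop(sprintf("config line %d is not key=value", which(bad)[1L]),
         call. = FALSE)
  }
  vals <- lapply(kv, function(x) trimws(paste(x[-1L], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[`, "", 1L))
  vals
}

num3 <- function(x) as.numeric(strsplit(as.character(x), ",")[[1L]])

#' Run the full spine-analysis pipeline
#'
#' Stages, in order: load stack and SWC model; rasterize the dendrite on
#' the image grid; compute the border distance map; detect seeds; apply
#' seed edits; segment heads; apply head edits (merge / remove); trace or
#' measure necks; apply retrace edits; assemble the spine table and
#' summary. Outputs written to `out_dir`: `seeds.csv`, `heads.tif`
#' (label stack), `necks.csv` (path voxels), `overlay.tif` (4-channel),
#' `spines.csv`, `summary.json` and `log.txt` (every parameter and
#' edit). A failing stage raises an error naming the stage. 2D
#' (single-slice) stacks are accepted up to segmentation, but neck
#' tracing refuses them (use `neck_mode = "straight_line"`).
#'
#' @param config named list (or path to a key=value file, see
#'   [read_run_config()]) with entries `stack` (TIFF path or
#'   `image_stack`), `swc` (path or `dendrite_model`), `out_dir`, and
#'   optionally `spacing`, `unit_scale`, detection/segmentation
#'   parameter overrides, `neck_mode` (`"traced"`/`"straight_line"`),
#'   `corridor_pad` and `edit_script`.
#' @return invisibly, a list with `seeds`, `heads`, `necks`, `records`,
#'   `summary` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg_num <- function(key, default) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  # no timestamps: outputs of a fixed config must be byte-identical
  log <- "spinemorph run"

  stack <- stage("input", {
    if (inherits(config$stack, "image_stack")) config$stack
    else read_stack(config$stack,
                    spacing = if (!is.null(config$spacing))
                      num3(config$spacing) else NULL)
  })
  model <- stage("input", {
    if (inherits(config$swc, "dendrite_model")) config$swc
    else read_swc(config$swc, unit_scale = cfg_num("unit_scale", 1))
  })
  out_dir <- config$out_dir %||% stop("config needs an out_dir",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  det <- stage("config", detection_params(
    intensity_min = cfg_num("intensity_min", 50),
    dist_min = cfg_num("dist_min", 0.2),
    dist_max = cfg_num("dist_max", 2.5),
    min_separation = cfg_num("min_separation", 0.5),
    smoothing_sigma = if (!is.null(config$smoothing_sigma))
      as.numeric(config$smoothing_sigma) else NULL))
  seg <- stage("config", segmentation_params(
    threshold_fraction = cfg_num("threshold_fraction", 0.5),
    radius_max = cfg_num("radius_max", 1.5),
    connectivity = as.integer(cfg_num("connectivity", 26)),
    background_quantile = cfg_num("background_quantile", 0.05)))
  neck_mode <- config$neck_mode %||% "traced"
  corridor_pad <- cfg_num("corridor_pad", 1)
  log <- c(log,
           sprintf("param: %s=%s",
                   c("intensity_min", "dist_min", "dist_max",
                     "min_separation", "threshold_fraction", "radius_max",
                     "connectivity", "background_quantile", "neck_mode"),
                   c(det$intensity_min, det$dist_min, det$dist_max,
                     det$min_separation, seg$threshold_fraction,
                     seg$radius_max, seg$connectivity,
                     seg$background_quantile, neck_mode)))

  edits <- if (!is.null(config$edit_script)) {
    stage("edits", parse_edit_script(config$edit_script))
  } else parse_edit_script(character())

  volume <- stage("rasterize", {
    rasterize_dendrite(model, stack$spacing, grid_shape = dim(stack$data))
  })
  bd <- stage("distance", border_distance_map(volume))
  state <- list(stack = stack, volume = volume, log = log)

  state$seeds <- stage("detection", {
    detect_local_maxima(stack, bd, det, dendrite_mask = volume$mask)
  })
  state$log <- c(state$log, sprintf("detection: %d seeds", nrow(state$seeds)))
  state <- stage("edits", {
    apply_edit_script(state, edits[edits$cmd %in% c("add_seed", "remove_seed"), ,
                                   drop = FALSE])
  })

  state$heads <- stage("segmentation", {
    if (nrow(state$seeds) == 0L) empty_heads(dim(stack$data), stack$spacing)
    else segment_heads(stack, state$seeds, volume, seg)
  })
  state <- stage("edits", {
    apply_edit_script(state, edits[edits$cmd %in% c("merge", "remove_head"), ,
                                   drop = FALSE])
  })

  state$necks <- stage("neck_tracing", {
    if (nrow(state$heads$info) == 0L) {
      list(paths = list(),
           table = data.frame(label = integer(), spine_type = character(),
                              neck_length = numeric(),
                              distance_to_dendrite = numeric(),
                              neck_mode = character()))
    } else {
      trace_all_necks(stack, state$heads, volume, mode = neck_mode,
                      corridor_pad = corridor_pad)
    }
  })
  state$neck_params <- list(mode = neck_mode, corridor_pad = corridor_pad)
  state <- stage("edits", {
    apply_edit_script(state, edits[edits$cmd == "retrace", , drop = FALSE])
  })

  records <- stage("measurements", spine_table(state$heads, state$necks))
  summary <- stage("measurements", {
    summarize_spines(records, dendrite_length(model))
  })

  stage("output", {
    write.csv(state$seeds, file.path(out_dir, "seeds.csv"),
              row.names = FALSE)
    write_stack(image_stack(state$heads$labels, stack$spacing,
                            bit_depth = 16L),
                file.path(out_dir, "heads.tif"))
    neck_rows <- list()
    for (lab in names(state$necks$paths)) {
      np <- state$necks$paths[[lab]]
      if (!is.null(np) && !is.null(np$voxels) && nrow(np$voxels) > 0L) {
        neck_rows[[lab]] <- data.frame(label = as.integer(lab),
                                       step = seq_len(nrow(np$voxels)),
                                       i = np$voxels[, 1L],
                                       j = np$voxels[, 2L],
                                       k = np$voxels[, 3L])
      }
    }
    neck_df <- if (length(neck_rows)) do.call(rbind, neck_rows) else
      data.frame(label = integer(), step = integer(), i = integer(),
                 j = integer(), k = integer())
    write.csv(neck_df, file.path(out_dir, "necks.csv"), row.names = FALSE)
    write_overlay(stack, volume, state$heads,
                  Filter(Negate(is.null), state$necks$paths),
                  path = file.path(out_dir, "overlay.tif"))
    write.csv(records, file.path(out_dir, "spines.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(state$log, sprintf("spines: %d", nrow(records))),
               file.path(out_dir, "log.txt"))
  })

  invisible(list(seeds = state$seeds, heads = state$heads,
                 necks = state$necks, records = records, summary = summary,
                 out_dir = out_dir))
}
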