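# Workflow composition: segment -> design -> assess, with a JSON config,
# per-stage logging to stderr, and a reproducibility manifest.

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

file_entry <- function(path) {
  list(path = basename(path), md5 = unname(tools::md5sum(path)),
       bytes = file.size(path))
}

#' Run the composed pipeline from a config
#'
#' Executes the stages named in the config in order — `phantom` (generate
#' synthetic inputs), `segment` (livewire volume segmentation to STL),
#' `design` (veneer CAD), `assess` (margin statistics and ANOVA) —
#' skipping stages whose block is absent or whose inputs are supplied
#' directly. Every produced file is listed in the returned manifest with
#' a content hash; identical configs and seeds reproduce identical hashes
#' for the deterministic stages.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#'   Recognised blocks: `out_dir`, `seed`, `phantom` (n, gap_mean_um,
#'   gap_sd_um, gap_model), `segment` (volume, anchors, out), `design`
#'   (incisor, tooth, out, insertion_axis, min_thickness, bevel_band,
#'   bevel_angle), `assess` (cutoff_um, pixel_size_um).
#' @return a `run_manifest` list (also written to `out_dir/manifest.json`)
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  out_dir <- cfg$out_dir %||% tempfile("veneerfit_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  manifest <- list(tool = "veneerfit",
                   version = as.character(utils::packageVersion("veneerfit")),
                   config = cfg, seed = seed, stages = list(), files = list())
  add_files <- function(paths) {
    for (p in paths) manifest$files[[basename(p)]] <<- file_entry(p)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[stage]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    res
  }

  batch <- NULL
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    batch <- timed("phantom", {
      log_stage("phantom", "generating %d veneers", ph$n %||% 15)
      make_phantom_batch(n = ph$n %||% 15L,
                         gap_mean = ph$gap_mean_um %||% 100,
                         gap_sd = ph$gap_sd_um %||% 50,
                         gap_model = ph$gap_model %||% "normal",
                         seed = seed, out_dir = file.path(out_dir, "phantom"))
    })
    add_files(list.files(file.path(out_dir, "phantom"), full.names = TRUE))
  }

  if (!is.null(cfg$segment)) {
    sg <- cfg$segment
    timed("segment", {
      log_stage("segment", "volume %s", sg$volume)
      vol <- load_volume(sg$volume)
      anchors <- read_anchors(sg$anchors)
      mesh <- segment_tooth(vol, anchors,
                            window = if (!is.null(sg$window))
                              intensity_window(sg$window[1], sg$window[2])
                            else NULL)
      outp <- file.path(out_dir, sg$out %||% "tooth.stl")
      write_mesh(mesh, outp)
      add_files(outp)
    })
  }

  if (!is.null(cfg$design)) {
    dg <- cfg$design
    timed("design", {
      log_stage("design", "incisor %s over tooth %s", dg$incisor, dg$tooth)
      incisor <- read_mesh(dg$incisor)
      tooth <- read_mesh(dg$tooth)
      des <- design_veneer(incisor, tooth,
                           insertion_axis = dg$insertion_axis %||% c(1, 0, 0),
                           min_thickness = dg$min_thickness %||% 0.5,
                           bevel_band = dg$bevel_band %||% 0.3,
                           bevel_angle = dg$bevel_angle %||% 45)
      outp <- file.path(out_dir, dg$out %||% "veneer.stl")
      write_mesh(des$veneer, outp)
      add_files(outp)
    })
  }

  if (!is.null(cfg$assess) && !is.null(batch)) {
    as_cfg <- cfg$assess
    timed("assess", {
      cutoff <- as_cfg$cutoff_um %||% 200
      stats <- assess_margin_batch(batch, cutoff = cutoff)
      outp <- file.path(out_dir, "margin_statistics.json")
      jsonlite::write_json(stats, outp, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      log_stage("assess", "overall mean %.1f um", stats$overall$mean)
      add_files(outp)
    })
  }

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest$path <- mp
  class(manifest) <- "run_manifest"
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure every margin of a phantom batch
#'
#' Runs [measure_marginal_gap()] on all rendered margin images of a
#' [make_phantom_batch()] result and aggregates: per-side per-veneer
#' readings (6 each), per-side means over veneers, pooled summary, and a
#' one-way ANOVA across sides.
#'
#' @param batch result of [make_phantom_batch()]
#' @param cutoff clinical cutoff in um
#' @return list: `readings` (long data.frame), `per_side` (side means and
#'   [summarize_gap()] summaries), `overall`, `anova`
#' @export
assess_margin_batch <- function(batch, cutoff = 200) {
  rows <- list()
  for (i in seq_along(batch$records)) {
    rec <- batch$records[[i]]
    for (s in names(rec$images)) {
      img <- rec$images[[s]]
      m <- measure_marginal_gap(img, attr(img, "pixel_size"), side = s,
                                image_id = sprintf("veneer%02d_%s", i, s))
      rows[[length(rows) + 1L]] <- data.frame(
        veneer = i, side = s, station = seq_along(m$readings),
        gap_um = m$readings)
    }
  }
  readings <- do.call(rbind, rows)
  sides <- split(readings$gap_um, readings$side)
  per_side <- lapply(sides, summarize_gap, cutoff = cutoff)
  list(readings = readings,
       per_side = per_side,
       side_means = vapply(per_side, `[[`, 0.0, "mean"),
       overall = summarize_gap(readings$gap_um, cutoff = cutoff),
       anova = one_way_anova(sides))
}

# --- segmentation driver ----------------------------------------------------

#' Read livewire anchors from a JSON-lines file
#'
#' Each line: `{"axis": 3, "slice": 12, "points": [[r,c], ...]}` with
#' 1-based pixel coordinates on the slice.
#'
#' @param path JSONL file
#' @return list of anchor records
#' @export
read_anchors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    list(axis = as.integer(rec$axis), slice = as.integer(rec$slice),
         points = matrix(as.numeric(rec$points), ncol = 2))
  })
}

slice_of <- function(vol, axis, index) {
  switch(axis,
         vol$data[index, , ],
         vol$data[, index, ],
         vol$data[, , index])
}

#' Segment a tooth from a volume with livewire contours
#'
#' For each anchor record, traces a livewire contour on the named slice,
#' fits the variational implicit surface to the contour set, rasterizes
#' the tooth mask on the volume frame, and extracts the surface mesh.
#'
#' @param vol a [voxel_volume()]
#' @param anchors list of `list(axis=, slice=, points=)` records (see
#'   [read_anchors()]); must span >= 2 distinct axes
#' @param window optional [intensity_window()] for preprocessing
#' @param median_radius preprocessing median radius (voxels)
#' @return a [triangle_mesh()] of the segmented tooth
#' @export
segment_tooth <- function(vol, anchors, window = NULL, median_radius = 1L) {
  contours <- lapply(anchors, function(a) {
    img <- slice_of(vol, a$axis, a$slice)
    trace_contour(img, a$points, window = window,
                  median_radius = median_radius,
                  plane_axis = a$axis, plane_index = a$slice)
  })
  cs <- contour_set(contours)
  surf <- fit_variational_surface(cs, vol)
  mask <- rasterize_mask(surf, vol)
  extract_surface_mesh(mask, name = "tooth")
}

# --- command-line interface -------------------------------------------------

#' Command-line entry point
#'
#' Verbs mirror the pipeline stages:
#' \preformatted{
#' veneerfit phantom --n 15 --gap-mean 100 --gap-sd 50 --seed 7 --out dir/
#' veneerfit segment --volume v.mhd --anchors a.jsonl --out tooth.stl
#' veneerfit design --incisor i.stl --tooth t.stl --out veneer.stl
#' veneerfit assess-margin --image m.mhd ... (via run config)
#' veneerfit run --config c.json
#' }
#'
#' @param args character vector (default: `commandArgs(trailingOnly=TRUE)`)
#' @return exit status, invisibly
#' @export
veneerfit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: veneerfit <phantom|segment|design|run> [--key value ...]")
    return(invisible(1L))
  }
  verb <- args[1]
  kv <- list()
  i <- 2L
  while (i <= length(args)) {
    k <- sub("^--", "", args[i])
    kv[[gsub("-", "_", k)]] <- if (i + 1 <= length(args)) args[i + 1] else ""
    i <- i + 2L
  }
  status <- 0L
  switch(verb,
    phantom = {
      make_phantom_batch(n = as.integer(kv$n %||% 15),
                         gap_mean = as.numeric(kv$gap_mean %||% 100),
                         gap_sd = as.numeric(kv$gap_sd %||% 50),
                         seed = as.integer(kv$seed %||% 7),
                         out_dir = kv$out %||% "phantom_out")
      log_stage("phantom", "wrote %s", kv$out %||% "phantom_out")
    },
    segment = {
      vol <- load_volume(kv$volume)
      mesh <- segment_tooth(vol, read_anchors(kv$anchors))
      write_mesh(mesh, kv$out %||% "tooth.stl")
    },
    design = {
      des <- design_veneer(read_mesh(kv$incisor), read_mesh(kv$tooth))
      write_mesh(des$veneer, kv$out %||% "veneer.stl")
    },
    run = {
      run_pipeline(kv$config)
    },
    {
      message("unknown verb: ", verb)
      status <- 1L
    })
  invisible(status)
}
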