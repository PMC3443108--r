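#' Write a tile set to disk as multi-page TIFFs
#'
#' One 32-bit float TIFF per tile per channel (one page per z-plane), named
#' `{sample}_{row}_{col}_{channel}.tif`, plus `{sample}_layout.json`
#' (acquisition geometry) and `{sample}_truth.csv` (planted ground truth, if
#' any).
#'
#' @param tiles a `tile_set`.
#' @param dir output directory (created if needed).
#' @param sample sample name used as the filename prefix.
#' @return invisibly, the vector of image files written.
#' @export
write_tileset <- function(tiles, dir, sample = "sample") {
  if (!inherits(tiles, "tile_set")) stop("`tiles` must be a tile_set", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # TIFF samples are stored in [0, 1]; rescale by the global intensity
  # maximum and record the factor in the layout metadata.
  scale <- max(1, vapply(tiles$tiles,
                         function(t) max(vapply(t$stacks, max, numeric(1))),
                         numeric(1)))
  files <- character(0)
  for (t in tiles$tiles) {
    for (ch in tiles$channels) {
      f <- file.path(dir, sprintf("%s_%d_%d_%s.tif", sample, t$row, t$col, ch))
      stack <- t$stacks[[ch]] / scale
      pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
      tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
      files <- c(files, f)
    }
  }
  layout <- tiles$layout
  meta <- list(sample = sample, grid_rows = layout$grid_rows,
               grid_cols = layout$grid_cols,
               tile_shape_px = layout$tile_shape_px,
               overlap_fraction = layout$overlap_fraction,
               channels = tiles$channels,
               pixel_size_um = tiles$pixel_size_um,
               z_step_um = tiles$z_step_um, n_planes = tiles$n_planes,
               intensity_scale = scale)
  jsonlite::write_json(meta, file.path(dir, paste0(sample, "_layout.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(tiles$truth) && nrow(tiles$truth)) {
    utils::write.csv(tiles$truth, file.path(dir, paste0(sample, "_truth.csv")),
                     row.names = FALSE)
  }
  invisible(files)
}

#' Read a tile set written by [write_tileset()]
#'
#' Reassembles the per-tile per-channel stacks from
#' `{sample}_{row}_{col}_{channel}.tif` files, validating that every expected
#' tile is present and that page counts and shapes are consistent. The total
#' number of TIFF pages read is recorded in the `pages_read` field.
#'
#' @param dir directory containing the files.
#' @param sample sample name prefix.
#' @return a `tile_set` (with `truth` if a truth CSV is present).
#' @export
read_tileset <- function(dir, sample = "sample") {
  meta_file <- file.path(dir, paste0(sample, "_layout.json"))
  if (!file.exists(meta_file)) stop("missing layout file: ", meta_file, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  tiles <- list()
  pages_read <- 0L
  shape <- NULL
  for (r in seq_len(meta$grid_rows)) {
    for (cc in seq_len(meta$grid_cols)) {
      stacks <- list()
      for (ch in meta$channels) {
        f <- file.path(dir, sprintf("%s_%d_%d_%s.tif", sample, r, cc, ch))
        if (!file.exists(f)) {
          stop(sprintf("missing tile file for (row %d, col %d, channel %s): %s",
                       r, cc, ch, basename(f)), call. = FALSE)
        }
        pages <- tiff::readTIFF(f, all = TRUE)
        pages_read <- pages_read + length(pages)
        if (length(pages) != meta$n_planes) {
          stop(sprintf("inconsistent page count in %s: %d planes, expected %d",
                       basename(f), length(pages), meta$n_planes), call. = FALSE)
        }
        this_shape <- dim(pages[[1]])
        if (is.null(shape)) shape <- this_shape
        if (!identical(shape, this_shape)) {
          stop("inconsistent tile shapes across files", call. = FALSE)
        }
        stacks[[ch]] <- array(unlist(pages), dim = c(shape, length(pages))) *
          (meta$intensity_scale %||% 1)
      }
      tiles[[length(tiles) + 1L]] <- list(row = r, col = cc, stacks = stacks)
    }
  }
  layout <- layout_tiles(meta$grid_rows, meta$grid_cols, meta$tile_shape_px,
                         meta$overlap_fraction)
  truth_file <- file.path(dir, paste0(sample, "_truth.csv"))
  truth <- if (file.exists(truth_file)) {
    utils::read.csv(truth_file)
  } else empty_truth()
  structure(list(tiles = tiles, layout = layout, channels = meta$channels,
                 pixel_size_um = meta$pixel_size_um, z_step_um = meta$z_step_um,
                 n_planes = meta$n_planes, truth = truth,
                 pages_read = pages_read),
            class = "tile_set")
}

#' Write a machine-readable and human-readable analysis report
#'
#' Serializes the results list to JSON with stable key ordering (byte
#' identical across repeated runs on identical inputs) and writes a plain
#' text summary next to it. If `results$counts` is a data frame with `group`
#' and `count` columns, a per-group summary is added.
#'
#' @param results named list of stage outputs.
#' @param path output path of the JSON report (`.txt` summary written
#'   alongside).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(results, path) {
  if (!is.null(results$counts) && is.data.frame(results$counts)) {
    results$group_summary <- group_summary(results$counts)
  }
  if (length(results)) results <- results[order(names(results))]
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  txt <- file.path(dirname(path), paste0(tools::file_path_sans_ext(basename(path)), ".txt"))
  lines <- c("plaquebeads report", "==================")
  for (nm in names(results)) {
    val <- results[[nm]]
    lines <- c(lines, "", nm, paste(utils::capture.output(print(val)), collapse = "\n"))
  }
  writeLines(lines, txt)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reads acquisition, detection, de-duplication, statistics and gating
#' settings, merging them over the package defaults.
#'
#' @param path YAML file.
#' @return list with elements `scene`, `detection`, `match_radius_um`,
#'   `gates`, `stats_direction`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scene_args <- raw$scene %||% list()
  det_args <- raw$detection %||% list()
  gate_args <- raw$gates %||% list()
  list(scene = do.call(scene_config, scene_args),
       detection = do.call(detection_params, det_args),
       match_radius_um = raw$match_radius_um %||% 1.5,
       gates = do.call(gate_params, gate_args),
       stats_direction = raw$stats_direction %||% "greater")
}
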