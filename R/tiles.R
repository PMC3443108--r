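#' Tile layout from grid geometry and overlap
#'
#' Computes row-major global pixel offsets for a rectangular acquisition grid
#' in which adjacent tiles share `overlap_fraction` of their extent: the step
#' between neighbouring offsets is `round((1 - overlap) * extent)` pixels, as
#' produced by a stage-driven tiling acquisition.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 1).
#' @param tile_shape_px integer `c(height, width)` of one tile in pixels.
#' @param overlap_fraction fraction of tile extent shared by neighbours
#'   (default 0.1, the 10 percent overlap used between adjacent z-stacks).
#' @return an object of class `tile_layout` with an `offsets` data frame
#'   (`row`, `col`, `x_px`, `y_px`; 0-based pixel offsets).
#' @export
layout_tiles <- function(grid_rows, grid_cols, tile_shape_px, overlap_fraction = 0.1) {
  if (grid_rows < 1 || grid_cols < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (length(tile_shape_px) != 2L || any(tile_shape_px <= 0)) {
    stop("`tile_shape_px` must be positive c(height, width)", call. = FALSE)
  }
  h <- as.integer(tile_shape_px[1]); w <- as.integer(tile_shape_px[2])
  step_y <- as.integer(round((1 - overlap_fraction) * h))
  step_x <- as.integer(round((1 - overlap_fraction) * w))
  grid <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  offsets <- data.frame(row = grid$row, col = grid$col,
                        x_px = (grid$col - 1L) * step_x,
                        y_px = (grid$row - 1L) * step_y)
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 tile_shape_px = c(h, w), overlap_fraction = overlap_fraction,
                 step_px = c(step_y, step_x), offsets = offsets),
            class = "tile_layout")
}

# Tile size along one axis: the largest integer W such that
# (k - 1) * round((1 - ov) * W) + W fits in n pixels.
tile_extent_px <- function(n, k, ov) {
  w <- floor(n / (1 + (k - 1) * (1 - ov)))
  while (w > 1 && (k - 1) * round((1 - ov) * w) + w > n) w <- w - 1L
  as.integer(w)
}

#' Crop a scene into an overlapping tile grid
#'
#' Cuts the scene into `grid_rows x grid_cols` z-stacks so that adjacent
#' tiles share `overlap_fraction` of their width/height, emulating a tiled
#' acquisition of the same specimen. Ground truth is carried along in global
#' micron coordinates.
#'
#' @param scene a `bead_scene`.
#' @param grid_rows,grid_cols grid dimensions.
#' @param overlap_fraction overlap between adjacent tiles (default 0.1).
#' @return an object of class `tile_set`: per-tile per-channel stacks plus the
#'   [layout_tiles()] geometry, acquisition metadata and the global truth.
#' @export
tile_scene <- function(scene, grid_rows, grid_cols, overlap_fraction = 0.1) {
  if (!inherits(scene, "bead_scene")) stop("`scene` must be a bead_scene", call. = FALSE)
  cfg <- scene$config
  th <- tile_extent_px(cfg$ny, grid_rows, overlap_fraction)
  tw <- tile_extent_px(cfg$nx, grid_cols, overlap_fraction)
  if (min(th, tw) * cfg$pixel_size_um < 2) {
    stop("tile size smaller than twice the bead diameter; use a coarser grid",
         call. = FALSE)
  }
  layout <- layout_tiles(grid_rows, grid_cols, c(th, tw), overlap_fraction)
  tiles <- vector("list", grid_rows * grid_cols)
  for (i in seq_len(nrow(layout$offsets))) {
    ox <- layout$offsets$x_px[i]; oy <- layout$offsets$y_px[i]
    stacks <- lapply(scene$volumes, function(v) {
      v[(oy + 1):(oy + th), (ox + 1):(ox + tw), , drop = FALSE]
    })
    tiles[[i]] <- list(row = layout$offsets$row[i], col = layout$offsets$col[i],
                       stacks = stacks)
  }
  structure(list(tiles = tiles, layout = layout,
                 channels = cfg$channels,
                 pixel_size_um = cfg$pixel_size_um, z_step_um = cfg$z_step_um,
                 n_planes = cfg$nz, truth = scene$truth),
            class = "tile_set")
}

tile_at <- function(tiles, row, col) {
  for (t in tiles$tiles) if (t$row == row && t$col == col) return(t)
  stop(sprintf("no tile at grid position (%d, %d)", row, col), call. = FALSE)
}
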