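#' Stitch tile projections into a composite image
#'
#' Places each tile's sum projection at its layout offset. Pixels covered by
#' more than one tile (the overlap strips) take the per-pixel maximum, so a
#' bead is never dimmed by averaging against a neighbouring tile's
#' background; ties keep the earlier (row-major) tile. A provenance map
#' records the winning tile for every pixel.
#'
#' @param tiles a `tile_set`.
#' @param channel channel name or index to stitch (default: all channels).
#' @return an object of class `composite`: named list `images` of stitched
#'   2D matrices, integer `provenance` matrix (row-major tile index), and the
#'   layout.
#' @export
stitch <- function(tiles, channel = NULL) {
  if (!inherits(tiles, "tile_set")) stop("`tiles` must be a tile_set", call. = FALSE)
  layout <- tiles$layout
  chans <- if (is.null(channel)) tiles$channels else tiles$channels[channel_index(tiles, channel)]
  th <- layout$tile_shape_px[1]; tw <- layout$tile_shape_px[2]
  H <- max(layout$offsets$y_px) + th
  W <- max(layout$offsets$x_px) + tw
  images <- lapply(chans, function(ch) matrix(-Inf, H, W))
  names(images) <- chans
  prov <- matrix(0L, H, W)
  for (i in seq_along(tiles$tiles)) {
    t <- tiles$tiles[[i]]
    off <- layout$offsets[layout$offsets$row == t$row & layout$offsets$col == t$col, ]
    ii <- (off$y_px + 1):(off$y_px + th)
    jj <- (off$x_px + 1):(off$x_px + tw)
    first <- TRUE
    for (ch in chans) {
      proj <- sum_projection(t$stacks[[ch]])
      cur <- images[[ch]][ii, jj]
      if (first) {
        win <- proj > cur
        pv <- prov[ii, jj]
        pv[win] <- i
        prov[ii, jj] <- pv
        first <- FALSE
      }
      images[[ch]][ii, jj] <- pmax(cur, proj)
    }
  }
  images <- lapply(images, function(m) { m[!is.finite(m)] <- 0; m })
  structure(list(images = images, provenance = prov, layout = layout,
                 pixel_size_um = tiles$pixel_size_um),
            class = "composite")
}

channel_index <- function(tiles, channel) {
  if (is.character(channel)) {
    i <- match(channel, tiles$channels)
    if (any(is.na(i))) stop("unknown channel: ", channel[is.na(i)][1], call. = FALSE)
    i
  } else as.integer(channel)
}

#' Map in-tile detections to global coordinates
#'
#' Adds the tile's layout offset to in-tile pixel coordinates and rescales to
#' microns, so detections from different tiles share one coordinate frame.
#'
#' @param detections data frame from [detect_spots()] with `tile_row` and
#'   `tile_col` columns.
#' @param layout a [layout_tiles()] object.
#' @param pixel_size_um lateral pixel size in microns.
#' @return `detections` with `x_px`, `y_px`, `x_um`, `y_um` replaced by global
#'   values (original in-tile pixel positions kept as `x_px_tile`,
#'   `y_px_tile`).
#' @export
to_global <- function(detections, layout, pixel_size_um) {
  if (!nrow(detections)) {
    detections$x_px_tile <- numeric(0); detections$y_px_tile <- numeric(0)
    return(detections)
  }
  key <- match(paste(detections$tile_row, detections$tile_col),
               paste(layout$offsets$row, layout$offsets$col))
  if (any(is.na(key))) stop("detection references a tile outside the grid", call. = FALSE)
  detections$x_px_tile <- detections$x_px
  detections$y_px_tile <- detections$y_px
  detections$x_px <- detections$x_px + layout$offsets$x_px[key]
  detections$y_px <- detections$y_px + layout$offsets$y_px[key]
  detections$x_um <- detections$x_px * pixel_size_um
  detections$y_um <- detections$y_px * pixel_size_um
  detections
}

#' De-duplicate detections repeated across overlapping tiles
#'
#' One physical bead lying in an overlap strip is detected once per adjacent
#' tile; this merges detections from *different* tiles whose global positions
#' fall within `match_radius_um`, keeping the brighter member. Same-tile
#' neighbours are never merged. The greedy pass runs in decreasing brightness
#' (ties broken on coordinates), so the result is independent of tile
#' processing order and idempotent.
#'
#' @param detections globally mapped detections (from [to_global()]).
#' @param match_radius_um merge radius in microns (default 1.5: one bead
#'   cannot produce two centres farther apart than the largest accepted
#'   diameter).
#' @return the unique subset of `detections`.
#' @export
deduplicate <- function(detections, match_radius_um = 1.5) {
  if (match_radius_um <= 0) stop("`match_radius_um` must be > 0", call. = FALSE)
  n <- nrow(detections)
  if (n <= 1L) return(detections)
  ord <- order(-detections$peak, detections$x_um, detections$y_um)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0); ktile <- character(0)
  tile_id <- paste(detections$tile_row, detections$tile_col)
  for (i in ord) {
    if (length(kx)) {
      dd <- sqrt((kx - detections$x_um[i])^2 + (ky - detections$y_um[i])^2)
      if (any(dd <= match_radius_um & ktile != tile_id[i])) next
    }
    keep[i] <- TRUE
    kx <- c(kx, detections$x_um[i]); ky <- c(ky, detections$y_um[i])
    ktile <- c(ktile, tile_id[i])
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect beads on every tile of a tile set
#'
#' Runs [sum_projection()] and [detect_spots()] on the bead channel of each
#' tile and maps the detections to global coordinates.
#'
#' @param tiles a `tile_set`.
#' @param params a [detection_params()].
#' @param channel bead channel name (default `"green_490_530"` if present,
#'   else channel 2).
#' @return globally mapped detection data frame with `tile_row`, `tile_col`.
#' @export
detect_tileset <- function(tiles, params = detection_params(), channel = NULL) {
  if (is.null(channel)) {
    channel <- if ("green_490_530" %in% tiles$channels) "green_490_530" else
      tiles$channels[min(2L, length(tiles$channels))]
  }
  res <- lapply(tiles$tiles, function(t) {
    det <- detect_spots(sum_projection(t$stacks[[channel]]), params, tiles$pixel_size_um)
    if (nrow(det)) { det$tile_row <- t$row; det$tile_col <- t$col }
    else { det$tile_row <- integer(0); det$tile_col <- integer(0) }
    det
  })
  det <- do.call(rbind, res)
  rownames(det) <- NULL
  to_global(det, tiles$layout, tiles$pixel_size_um)
}

#' End-to-end bead count for one sample
#'
#' The full counting pipeline for one tiled acquisition: sum-project each
#' tile's bead channel, detect bead-sized spots, map them to global
#' coordinates, remove overlap duplicates, and count.
#'
#' @inheritParams detect_tileset
#' @param match_radius_um de-duplication radius (default
#'   `params$max_diameter_um`).
#' @return non-negative integer bead count.
#' @export
count_sample <- function(tiles, params = detection_params(),
                         match_radius_um = params$max_diameter_um) {
  nrow(deduplicate(detect_tileset(tiles, params), match_radius_um))
}
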