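#' Detection parameters for bead-sized spots
#'
#' Physical diameter bounds and the brightness-above-background threshold of
#' the spot counter. The 0.5-1.5 um diameter window brackets the observed
#' image size of 1-um beads in tissue; the threshold is in intensity units
#' above the local (median-filtered) background and is normally set with
#' [calibrate_threshold()] against reference counts.
#'
#' @param min_diameter_um,max_diameter_um equivalent-diameter bounds in
#'   microns (defaults 0.5 and 1.5).
#' @param threshold intensity above local background required for a pixel to
#'   join a spot (default 10).
#' @param local_background_radius_um radius of the median filter used to
#'   estimate local background (default 5 um).
#' @param max_clump_diameter_um components above `max_diameter_um` that
#'   cannot be split are still emitted, flagged as clumps, up to this size
#'   (default 2.4 um, the footprint of 2-3 clumped 1-um beads); anything
#'   larger is rejected as a non-bead structure.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(min_diameter_um = 0.5, max_diameter_um = 1.5,
                             threshold = 10, local_background_radius_um = 5,
                             max_clump_diameter_um = 2.4) {
  if (!(min_diameter_um > 0 && min_diameter_um < max_diameter_um)) {
    stop("need 0 < min_diameter_um < max_diameter_um", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  structure(list(min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 threshold = threshold,
                 local_background_radius_um = local_background_radius_um,
                 max_clump_diameter_um = max_clump_diameter_um),
            class = "detection_params")
}

#' Sum projection of a z-stack
#'
#' Pixelwise sum over the axial dimension; bead quantification operates on
#' the sum projection of each individual z-stack.
#'
#' @param stack a 3D array (`ny x nx x nz`, `nz >= 1`) or a single-plane
#'   matrix.
#' @return a numeric matrix.
#' @export
sum_projection <- function(stack) {
  if (is.matrix(stack)) return(stack + 0)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) {
    stop("`stack` must be a 3D array with at least one plane", call. = FALSE)
  }
  rowSums(stack, dims = 2)
}

eq_diameter_um <- function(area_px, pixel_size_um) {
  2 * sqrt(area_px / pi) * pixel_size_um
}

# Pruned internal intensity maxima of one component: pixels that are >= all
# 8 neighbours, at least half the component peak, thinned greedily so kept
# maxima are >= min_sep_px apart. Returns a matrix of (row, col) positions.
component_maxima <- function(sub, rows, cols, min_sep_px) {
  nr <- nrow(sub); nc <- ncol(sub)
  vals <- sub[cbind(rows, cols)]
  peak <- max(vals)
  inset <- matrix(FALSE, nr, nc); inset[cbind(rows, cols)] <- TRUE
  is_max <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (vals[i] < 0.5 * peak) next
    r <- rows[i]; cc <- cols[i]
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
          inset[rr, c2] && sub[rr, c2] > vals[i]) ok <- FALSE
    }
    is_max[i] <- ok
  }
  cand <- which(is_max)
  cand <- cand[order(-vals[cand], rows[cand], cols[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) ||
        min(sqrt((rows[kept] - rows[i])^2 + (cols[kept] - cols[i])^2)) >= min_sep_px) {
      kept <- c(kept, i)
    }
  }
  cbind(rows[kept], cols[kept])
}

detection_row <- function(sub, rows, cols, level, pixel_size_um, clump) {
  vals <- sub[cbind(rows, cols)]
  core <- vals >= level
  if (!any(core)) core <- vals >= max(vals)   # degenerate: keep the peak pixel
  w <- vals[core]
  x_px <- sum(w * (cols[core] - 0.5)) / sum(w)
  y_px <- sum(w * (rows[core] - 0.5)) / sum(w)
  data.frame(x_px = x_px, y_px = y_px,
             x_um = x_px * pixel_size_um, y_um = y_px * pixel_size_um,
             peak = max(vals),
             eq_diameter_um = eq_diameter_um(sum(core), pixel_size_um),
             area_px = sum(core), clump = clump, z_best = NA_integer_)
}

#' Detect bead-sized spots in a projection image
#'
#' Subtracts a median-filtered local background, thresholds, labels
#' 8-connected components, and measures each component at its half-peak level
#' (never below the threshold), which makes the measured equivalent diameter
#' insensitive to the threshold/peak ratio. Components within the diameter
#' bounds are emitted with intensity-weighted sub-pixel centroids. Over-size
#' components are split at 2-3 pruned internal intensity maxima when
#' separable; unsplittable over-size components up to
#' `max_clump_diameter_um` are emitted once and flagged as clumps, larger
#' ones rejected.
#'
#' @param image 2D numeric matrix (a sum projection).
#' @param params a [detection_params()].
#' @param pixel_size_um lateral pixel size in microns.
#' @return a data frame of detections: `x_px`, `y_px` (in-tile 0-based pixel
#'   coordinates, sub-pixel), `x_um`, `y_um`, `peak` (intensity above
#'   background), `eq_diameter_um`, `area_px`, `clump`, `z_best` (NA until
#'   assigned). Zero rows on a blank image.
#' @export
detect_spots <- function(image, params = detection_params(), pixel_size_um = 0.25) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  bg <- local_background(image, params$local_background_radius_um / pixel_size_um)
  sub <- image - bg
  mask <- sub > params$threshold
  if (!any(mask)) return(empty_detections())
  lab <- label_components(mask)
  min_sep_px <- params$min_diameter_um / pixel_size_um
  out <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    rows <- idx[, 1]; cols <- idx[, 2]
    vals <- sub[idx]
    peak <- max(vals)
    level <- max(params$threshold, 0.5 * peak)
    d <- eq_diameter_um(sum(vals >= level), pixel_size_um)
    if (d < params$min_diameter_um) next
    if (d <= params$max_diameter_um) {
      out[[length(out) + 1L]] <- detection_row(sub, rows, cols, level, pixel_size_um, FALSE)
      next
    }
    # over-size: try splitting at internal maxima
    mx <- component_maxima(sub, rows, cols, min_sep_px)
    if (nrow(mx) %in% c(2L, 3L)) {
      d2 <- outer(rows, mx[, 1], function(a, b) (a - b)^2) +
        outer(cols, mx[, 2], function(a, b) (a - b)^2)
      frag <- max.col(-d2, ties.method = "first")
      for (f in seq_len(nrow(mx))) {
        sel <- frag == f
        if (!any(sel)) next
        fpeak <- max(vals[sel])
        flevel <- max(params$threshold, 0.5 * fpeak)
        fd <- eq_diameter_um(sum(vals[sel] >= flevel), pixel_size_um)
        if (fd < params$min_diameter_um) next
        if (fd <= params$max_diameter_um) {
          out[[length(out) + 1L]] <-
            detection_row(sub, rows[sel], cols[sel], flevel, pixel_size_um, FALSE)
        } else if (fd <= params$max_clump_diameter_um) {
          out[[length(out) + 1L]] <-
            detection_row(sub, rows[sel], cols[sel], flevel, pixel_size_um, TRUE)
        }
      }
    } else if (d <= params$max_clump_diameter_um) {
      out[[length(out) + 1L]] <- detection_row(sub, rows, cols, level, pixel_size_um, TRUE)
    }
  }
  if (!length(out)) return(empty_detections())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_detections <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
             y_um = numeric(0), peak = numeric(0), eq_diameter_um = numeric(0),
             area_px = integer(0), clump = logical(0), z_best = integer(0))
}

#' Calibrate the detection threshold against reference counts
#'
#' Mirrors the manual calibration of the counting algorithm: the threshold is
#' varied over a grid on representative projections until the agreement
#' between algorithm counts and reference (visual-inspection) counts is
#' optimal. Agreement is summed absolute count error; ties break toward the
#' smallest threshold.
#'
#' @param projections list of 2D projection images.
#' @param reference_counts integer vector, one reference count per image.
#' @param threshold_grid candidate thresholds.
#' @param params a [detection_params()]; its `threshold` is overridden by each
#'   grid value.
#' @param pixel_size_um lateral pixel size in microns.
#' @return the selected threshold (scalar).
#' @export
calibrate_threshold <- function(projections, reference_counts, threshold_grid,
                                params = detection_params(), pixel_size_um = 0.25) {
  if (!length(projections) || length(projections) != length(reference_counts)) {
    stop("`projections` and `reference_counts` must be non-empty and equal length",
         call. = FALSE)
  }
  if (!length(threshold_grid)) stop("`threshold_grid` must be non-empty", call. = FALSE)
  err <- vapply(threshold_grid, function(thr) {
    p <- params; p$threshold <- thr
    sum(abs(vapply(projections, function(img) {
      nrow(detect_spots(img, p, pixel_size_um))
    }, numeric(1)) - reference_counts))
  }, numeric(1))
  min(threshold_grid[err == min(err)])
}

#' Best-focus plane of a detection
#'
#' Scans the axial intensity profile of a detection's footprint and returns
#' the plane where the bead's background-subtracted signal is brightest. A
#' higher threshold than the detection threshold is used here so that only
#' the plane of best focus survives, collapsing the axially smeared bead
#' signal to a single section.
#'
#' @param stack the 3D stack (`ny x nx x nz`) the detection came from.
#' @param detection one row of a [detect_spots()] data frame.
#' @param focus_threshold minimum mean footprint signal above local background
#'   for a plane to qualify; if no plane qualifies, `NA_integer_`.
#' @param pixel_size_um lateral pixel size in microns.
#' @return 1-based z index of the best-focus plane, or `NA_integer_`; ties
#'   break toward the lowest index.
#' @export
best_focus_plane <- function(stack, detection, focus_threshold = 0,
                             pixel_size_um = 0.25) {
  d <- dim(stack)
  if (length(d) != 3L) stop("`stack` must be a 3D array", call. = FALSE)
  r_px <- max(detection$eq_diameter_um / 2 / pixel_size_um, 1)
  ci <- floor(detection$y_px) + 1L
  cj <- floor(detection$x_px) + 1L
  if (ci < 1 || ci > d[1] || cj < 1 || cj > d[2]) {
    stop("detection footprint lies outside the stack", call. = FALSE)
  }
  half <- ceiling(r_px)
  ii <- max(1, ci - half):min(d[1], ci + half)
  jj <- max(1, cj - half):min(d[2], cj + half)
  foot <- outer(((ii - 0.5) - detection$y_px)^2,
                ((jj - 0.5) - detection$x_px)^2, "+") <= r_px^2 + 1e-9
  bh <- half + 8L  # background window: footprint plus an annulus
  bi <- max(1, ci - bh):min(d[1], ci + bh)
  bj <- max(1, cj - bh):min(d[2], cj + bh)
  prof <- vapply(seq_len(d[3]), function(k) {
    plane <- stack[, , k]
    mean(plane[ii, jj][foot]) - stats::median(plane[bi, bj])
  }, numeric(1))
  if (max(prof) < focus_threshold) return(NA_integer_)
  which.max(prof)
}

#' Assign best-focus planes to a set of detections
#'
#' Convenience wrapper applying [best_focus_plane()] to every detection of a
#' tile stack, filling the `z_best` column.
#'
#' @param stack the tile's bead-channel 3D stack.
#' @param detections data frame from [detect_spots()].
#' @inheritParams best_focus_plane
#' @return `detections` with `z_best` filled (NA where no plane qualified).
#' @export
assign_best_focus <- function(stack, detections, focus_threshold = 0,
                              pixel_size_um = 0.25) {
  if (!nrow(detections)) return(detections)
  detections$z_best <- vapply(seq_len(nrow(detections)), function(i) {
    best_focus_plane(stack, detections[i, ], focus_threshold, pixel_size_um)
  }, integer(1))
  detections
}

#' Calibrate the counting threshold on representative samples
#'
#' Sample-level analogue of [calibrate_threshold()]: for each candidate
#' threshold the full counting pipeline ([count_sample()]) is run on a small
#' number of representative tiled acquisitions (in practice two, one
#' low-count and one high-count composite), and the threshold minimizing the
#' summed absolute disagreement with the reference counts is returned, ties
#' toward the smallest value. The reference counts play the role of
#' visual-inspection counts.
#'
#' @param samples list of `tile_set` objects.
#' @param reference_counts integer vector of reference bead counts.
#' @param threshold_grid candidate thresholds.
#' @param params a [detection_params()]; `threshold` is overridden.
#' @return the selected threshold.
#' @export
calibrate_count_threshold <- function(samples, reference_counts, threshold_grid,
                                      params = detection_params()) {
  if (!length(samples) || length(samples) != length(reference_counts)) {
    stop("`samples` and `reference_counts` must be non-empty and equal length",
         call. = FALSE)
  }
  if (!length(threshold_grid)) stop("`threshold_grid` must be non-empty", call. = FALSE)
  err <- vapply(threshold_grid, function(thr) {
    p <- params; p$threshold <- thr
    sum(abs(vapply(samples, count_sample, numeric(1), params = p) - reference_counts))
  }, numeric(1))
  min(threshold_grid[err == min(err)])
}
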