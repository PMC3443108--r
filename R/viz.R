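#' Axial-distortion-corrected reconstruction
#'
#' Builds a stitched composite volume in which the bead channel is zeroed and
#' each detected bead is re-rendered as a uniform disk in its single plane of
#' best focus, collapsing the axially smeared bead signal; the structural
#' channels are stitched through unchanged. Every detection must carry a
#' `z_best` (see [assign_best_focus()]).
#'
#' @param tiles a `tile_set`.
#' @param detections globally mapped detections with `z_best` set.
#' @param marker_diameter_um diameter of the replacement bead marker
#'   (default 1, the physical bead diameter).
#' @return object of class `corrected_volume`: named list `volumes` of 3D
#'   arrays plus `marker_diameter_um`.
#' @export
reconstruct_corrected <- function(tiles, detections, marker_diameter_um = 1) {
  if (!inherits(tiles, "tile_set")) stop("`tiles` must be a tile_set", call. = FALSE)
  if (nrow(detections) && any(is.na(detections$z_best))) {
    stop("every detection needs `z_best`; run assign_best_focus() first", call. = FALSE)
  }
  layout <- tiles$layout
  th <- layout$tile_shape_px[1]; tw <- layout$tile_shape_px[2]
  H <- max(layout$offsets$y_px) + th
  W <- max(layout$offsets$x_px) + tw
  nz <- tiles$n_planes
  bead_ch <- if ("green_490_530" %in% tiles$channels) "green_490_530" else
    tiles$channels[min(2L, length(tiles$channels))]
  volumes <- lapply(tiles$channels, function(ch) array(0, dim = c(H, W, nz)))
  names(volumes) <- tiles$channels
  for (t in tiles$tiles) {
    off <- layout$offsets[layout$offsets$row == t$row & layout$offsets$col == t$col, ]
    ii <- (off$y_px + 1):(off$y_px + th); jj <- (off$x_px + 1):(off$x_px + tw)
    for (ch in setdiff(tiles$channels, bead_ch)) {
      volumes[[ch]][ii, jj, ] <- pmax(volumes[[ch]][ii, jj, ], t$stacks[[ch]])
    }
  }
  r_px <- marker_diameter_um / 2 / tiles$pixel_size_um
  for (i in seq_len(nrow(detections))) {
    k <- detections$z_best[i]
    volumes[[bead_ch]][, , k] <- stamp_disk(
      volumes[[bead_ch]][, , k], detections$x_px[i], detections$y_px[i],
      r_px, detections$peak[i])
  }
  structure(list(volumes = volumes, marker_diameter_um = marker_diameter_um,
                 bead_channel = bead_ch),
            class = "corrected_volume")
}

#' Dilate detections for display
#'
#' Stamps binary disks of a display diameter (default 20 um) at detection
#' centres over an image so sparse 1-um beads become visible at plaque scale.
#' Overlapping stamps merge as a union; stamped pixels are set to
#' `mask_value`, never summed.
#'
#' @param image 2D matrix (e.g. a stitched composite channel).
#' @param detections detections with `x_px`, `y_px` in the image's frame.
#' @param display_diameter_um display diameter in microns (default 20).
#' @param pixel_size_um lateral pixel size in microns.
#' @param mask_value value assigned to stamped pixels (default: image max,
#'   or 1 on a blank image).
#' @return the overlay image.
#' @export
dilate_detections <- function(image, detections, display_diameter_um = 20,
                              pixel_size_um = 0.25, mask_value = NULL) {
  stopifnot_scalar(display_diameter_um, "display_diameter_um", positive = TRUE)
  if (is.null(mask_value)) mask_value <- max(max(image), 1)
  r_px <- display_diameter_um / 2 / pixel_size_um
  out <- image
  for (i in seq_len(nrow(detections))) {
    out <- stamp_disk(out, detections$x_px[i], detections$y_px[i], r_px, mask_value)
  }
  out
}

#' Gaussian smoothing with fixed kernel support
#'
#' Convolves an image with a normalized `kernel_px x kernel_px` Gaussian
#' (default 7x7) for presentation of the structural channels. The kernel
#' sigma defaults to `kernel_px / 6` so the support covers about +/- 3 sigma.
#'
#' @param image 2D matrix.
#' @param kernel_px odd kernel size >= 3.
#' @param sigma_px Gaussian sigma in pixels.
#' @return the smoothed image (mean preserved; circular boundary).
#' @export
smooth_channel <- function(image, kernel_px = 7, sigma_px = kernel_px / 6) {
  if (kernel_px < 3 || kernel_px %% 2 == 0) {
    stop("`kernel_px` must be an odd integer >= 3", call. = FALSE)
  }
  d <- seq_len(kernel_px) - (kernel_px + 1) / 2
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma_px^2))
  k <- k / sum(k)
  m <- EBImage::filter2(image, k)
  matrix(as.numeric(m), nrow(image), ncol(image))
}
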