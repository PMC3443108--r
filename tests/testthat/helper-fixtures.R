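# Shared fixtures: all synthetic, built in code at test time.

# A configuration with no background texture and no noise, so volumes carry
# only the planted bead signal.
clean_config <- function(width_um = 40, height_um = 40, depth_um = 30,
                         pixel_size_um = 0.25, z_step_um = 10) {
  scene_config(
    width_um = width_um, height_um = height_um, depth_um = depth_um,
    pixel_size_um = pixel_size_um, z_step_um = z_step_um,
    background = list(
      list(fiber_density = 0, amplitude = 0),
      list(mean = 0, fiber_amplitude = 0, fiber_density = 0),
      list(blob_density = 0, amplitude = 0)),
    noise = list(read_sigma = 0, photons_per_unit = 0))
}

# Noise-free scene with n well-separated in-range beads.
clean_scene <- function(n_beads, seed = 1, width_um = 40, height_um = 40,
                        clump_fraction = 0, ...) {
  sc <- generate_scene(clean_config(width_um = width_um, height_um = height_um, ...),
                       seed = seed)
  plant_beads(sc, n_beads, seed = seed + 1000, clump_fraction = clump_fraction)
}

# Stamp a sharp (unblurred) disk of given diameter (um) into a matrix at
# continuous pixel position; used to build detector test images with exactly
# known sizes.
add_sharp_disk <- function(img, x_px, y_px, diameter_um, value, pixel_size_um = 0.25) {
  r_px <- diameter_um / 2 / pixel_size_um
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (((i - 0.5) - y_px)^2 + ((j - 0.5) - x_px)^2 <= r_px^2) {
        img[i, j] <- img[i, j] + value
      }
    }
  }
  img
}

# Fetch the tile at a grid position (tests only).
tile_at_test <- function(ts, row, col) {
  for (t in ts$tiles) if (t$row == row && t$col == col) return(t)
  stop("no such tile")
}
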