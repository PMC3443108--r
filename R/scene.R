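#' Scene configuration for synthetic plaque volumes
#'
#' Describes the physical extents and sampling of a simulated three-channel
#' multiphoton volume of an atherosclerotic plaque: a collagen
#' second-harmonic band (fibrous texture), an elastin/autofluorescence band
#' that also carries the bead signal, and a neutral-lipid band (blob texture).
#'
#' The voxel grid is `ceil(extent / step)` in each axis; voxel `(i, j, k)`
#' covers the half-open physical interval `[(i-1)*s, i*s)` so continuous
#' micron coordinates are 0-based at the volume corner.
#'
#' @param width_um,height_um,depth_um physical extents in microns.
#' @param pixel_size_um lateral sampling (microns per pixel). The default of
#'   0.25 um/px makes a 1-um bead span about 4 pixels, so the 0.5-1.5 um
#'   detection diameter bounds map to multi-pixel structures.
#' @param z_step_um axial step between optical sections in microns (default
#'   10, the tiling acquisition step).
#' @param channels ordered channel labels. The first channel receives fiber
#'   texture, the second diffuse autofluorescence (plus faint fibers) and the
#'   planted beads, the third blob texture.
#' @param background per-channel texture parameters; see Details.
#' @param noise list with `read_sigma` (Gaussian read noise, intensity units)
#'   and `photons_per_unit` (Poisson scaling; 0 disables shot noise).
#'
#' @details `background` is a list with one entry per channel (matched by
#'   position) holding: for channel 1 `fiber_density` (fibers per 1000 um^2)
#'   and `amplitude`; for channel 2 `mean` (diffuse level), `fiber_amplitude`
#'   and `fiber_density`; for channel 3 `blob_density` (blobs per 1000 um^2),
#'   `amplitude` and `sigma_um`. Setting all amplitudes/means to zero yields
#'   empty volumes (useful for noise-free ground-truth work).
#'
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(width_um = 80, height_um = 80, depth_um = 30,
                         pixel_size_um = 0.25, z_step_um = 10,
                         channels = c("shg_380_440", "green_490_530", "red_530_650"),
                         background = NULL,
                         noise = list(read_sigma = 1, photons_per_unit = 5)) {
  for (nm in c("width_um", "height_um", "depth_um", "pixel_size_um", "z_step_um")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  if (length(channels) < 1L) stop("at least one channel is required", call. = FALSE)
  if (is.null(background)) {
    background <- list(
      list(fiber_density = 0.4, amplitude = 12),
      list(mean = 15, fiber_amplitude = 4, fiber_density = 0.2),
      list(blob_density = 0.15, amplitude = 10, sigma_um = 4)
    )
  }
  if (is.null(noise$read_sigma)) noise$read_sigma <- 0
  if (is.null(noise$photons_per_unit)) noise$photons_per_unit <- 0
  cfg <- list(
    width_um = width_um, height_um = height_um, depth_um = depth_um,
    pixel_size_um = pixel_size_um, z_step_um = z_step_um,
    channels = as.character(channels), background = background, noise = noise,
    nx = as.integer(ceiling(width_um / pixel_size_um)),
    ny = as.integer(ceiling(height_um / pixel_size_um)),
    nz = as.integer(ceiling(depth_um / z_step_um))
  )
  class(cfg) <- "scene_config"
  cfg
}

#' Physical description of a fluorescent bead and its imaged profile
#'
#' A bead is rendered as a uniform disk of its physical diameter convolved
#' with an anisotropic Gaussian point-spread function. The axial sigma
#' defaults to 5 um: with the 10 um axial step of the tiling acquisition this
#' reproduces the instrument's property that a single bead carries
#' above-threshold signal in at least two adjacent optical sections, and the
#' pronounced axial elongation seen in low-NA deep-tissue reconstructions.
#'
#' @param diameter_um physical bead diameter (default 1 um microspheres).
#' @param peak_intensity amplitude above background, arbitrary units.
#' @param lateral_sigma_um lateral PSF sigma in microns.
#' @param axial_sigma_um axial PSF sigma in microns; must be >= lateral.
#' @return an object of class `bead_spec`.
#' @export
bead_spec <- function(diameter_um = 1, peak_intensity = 100,
                      lateral_sigma_um = 0.3, axial_sigma_um = 5) {
  stopifnot_scalar(diameter_um, "diameter_um", positive = TRUE)
  stopifnot_scalar(peak_intensity, "peak_intensity", positive = TRUE)
  stopifnot_scalar(lateral_sigma_um, "lateral_sigma_um", positive = TRUE)
  stopifnot_scalar(axial_sigma_um, "axial_sigma_um", positive = TRUE)
  if (axial_sigma_um < lateral_sigma_um) {
    stop("axial_sigma_um must be >= lateral_sigma_um (axial elongation)", call. = FALSE)
  }
  structure(list(diameter_um = diameter_um, peak_intensity = peak_intensity,
                 lateral_sigma_um = lateral_sigma_um, axial_sigma_um = axial_sigma_um),
            class = "bead_spec")
}

empty_truth <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             clump_id = integer(0))
}

# Render faint fibrous texture: random line segments stamped into single
# z-planes, then blurred laterally.
render_fibers <- function(ny, nx, nz, n_fibers, amplitude, pixel_size_um) {
  vol <- array(0, dim = c(ny, nx, nz))
  if (n_fibers < 1 || amplitude <= 0) return(vol)
  for (f in seq_len(n_fibers)) {
    k <- sample.int(nz, 1)
    x0 <- runif(1, 0, nx); y0 <- runif(1, 0, ny)
    theta <- runif(1, 0, pi)
    len_px <- runif(1, 10, min(nx, ny) * 0.6)
    tt <- seq(0, len_px, by = 1)
    xs <- pmin(pmax(round(x0 + tt * cos(theta)), 1), nx)
    ys <- pmin(pmax(round(y0 + tt * sin(theta)), 1), ny)
    idx <- cbind(ys, xs)
    plane <- vol[, , k]
    plane[idx] <- plane[idx] + 1
    vol[, , k] <- plane
  }
  for (k in seq_len(nz)) {
    if (max(vol[, , k]) > 0) {
      sm <- EBImage::gblur(vol[, , k], sigma = 2)
      vol[, , k] <- sm / max(sm) * amplitude
    }
  }
  vol
}

# Diffuse autofluorescence: constant mean modulated by low-frequency noise.
render_diffuse <- function(ny, nx, nz, mean_level) {
  vol <- array(0, dim = c(ny, nx, nz))
  if (mean_level <= 0) return(vol)
  # keep the blur kernel inside the image for small fields
  sigma <- max(1, min(8, (min(ny, nx) - 1) / 7))
  for (k in seq_len(nz)) {
    field <- matrix(rnorm(ny * nx), ny, nx)
    field <- EBImage::gblur(field, sigma = sigma)
    field <- field / max(abs(field), 1e-12) * 0.3
    vol[, , k] <- mean_level * (1 + field)
  }
  pmax(vol, 0)
}

# Lipid blobs: isotropic lateral Gaussians with a broad axial envelope.
render_blobs <- function(ny, nx, nz, n_blobs, amplitude, sigma_px, z_step_um) {
  vol <- array(0, dim = c(ny, nx, nz))
  if (n_blobs < 1 || amplitude <= 0) return(vol)
  axial_sigma_um <- 8
  for (b in seq_len(n_blobs)) {
    xc <- runif(1, 0, nx); yc <- runif(1, 0, ny)
    zc <- runif(1, 0, nz * z_step_um)
    amp <- amplitude * runif(1, 0.5, 1.5)
    half <- ceiling(3 * sigma_px)
    ii <- max(1, floor(yc - half)):min(ny, ceiling(yc + half))
    jj <- max(1, floor(xc - half)):min(nx, ceiling(xc + half))
    lat <- outer(((ii - 0.5) - yc)^2, ((jj - 0.5) - xc)^2, "+")
    lat <- exp(-lat / (2 * sigma_px^2))
    for (k in seq_len(nz)) {
      dz <- (k - 0.5) * z_step_um - zc
      w <- exp(-dz^2 / (2 * axial_sigma_um^2))
      if (w > 1e-3) vol[ii, jj, k] <- vol[ii, jj, k] + amp * w * lat
    }
  }
  vol
}

#' Generate a synthetic three-channel plaque volume
#'
#' Renders per-channel background texture (fibers / diffuse autofluorescence /
#' blobs), then applies a photon-limited noise model: Poisson shot noise on
#' the scaled signal plus Gaussian read noise, clipped at zero. The returned
#' scene carries an empty ground-truth table; beads are added with
#' [plant_beads()].
#'
#' @param config a [scene_config()].
#' @param seed integer seed; identical `(config, seed)` give voxelwise
#'   identical scenes.
#' @return an object of class `bead_scene` with fields `config`, `volumes`
#'   (named list of `ny x nx x nz` arrays) and `truth`.
#' @export
generate_scene <- function(config, seed = 1) {
  if (!inherits(config, "scene_config")) stop("`config` must be a scene_config", call. = FALSE)
  ny <- config$ny; nx <- config$nx; nz <- config$nz
  area_factor <- config$width_um * config$height_um / 1000  # densities per 1000 um^2
  volumes <- with_seed(seed, {
    out <- vector("list", length(config$channels))
    names(out) <- config$channels
    for (ci in seq_along(config$channels)) {
      bg <- config$background[[min(ci, length(config$background))]]
      vol <- if (ci == 1L) {
        render_fibers(ny, nx, nz,
                      n_fibers = round((bg$fiber_density %||% 0) * area_factor),
                      amplitude = bg$amplitude %||% 0,
                      pixel_size_um = config$pixel_size_um)
      } else if (ci == 2L) {
        v <- render_diffuse(ny, nx, nz, bg$mean %||% 0)
        fa <- bg$fiber_amplitude %||% 0
        if (fa > 0) {
          v <- v + render_fibers(ny, nx, nz,
                                 n_fibers = round((bg$fiber_density %||% 0) * area_factor),
                                 amplitude = fa, pixel_size_um = config$pixel_size_um)
        }
        v
      } else {
        render_blobs(ny, nx, nz,
                     n_blobs = round((bg$blob_density %||% 0) * area_factor),
                     amplitude = bg$amplitude %||% 0,
                     sigma_px = (bg$sigma_um %||% 4) / config$pixel_size_um,
                     z_step_um = config$z_step_um)
      }
      out[[ci]] <- apply_noise(vol, config$noise)
    }
    out
  })
  structure(list(config = config, volumes = volumes, truth = empty_truth()),
            class = "bead_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_noise <- function(vol, noise) {
  ppu <- noise$photons_per_unit %||% 0
  rs <- noise$read_sigma %||% 0
  vol <- pmax(vol, 0)  # smoothing can leave tiny negative edge values
  if (ppu > 0 && max(vol) > 0) {
    vol <- array(stats::rpois(length(vol), lambda = as.vector(vol) * ppu) / ppu,
                 dim = dim(vol))
  }
  if (rs > 0) {
    vol <- vol + array(stats::rnorm(length(vol), 0, rs), dim = dim(vol))
  }
  pmax(vol, 0)
}

# Lateral profile of a uniform disk of radius R convolved with a Gaussian of
# sigma s, approximated by the error-function edge model; ~1 at the centre,
# 0.5 at the disk edge.
bead_lateral_profile <- function(r, R, s) stats::pnorm((R - r) / s)

# Add one bead's signal into the bead channel of `volumes`.
render_bead <- function(vol, x_um, y_um, z_um, spec, config) {
  px <- config$pixel_size_um
  R <- spec$diameter_um / 2
  lat_half_um <- R + 4 * spec$lateral_sigma_um
  nr <- dim(vol)[1]; ncl <- dim(vol)[2]; nz <- dim(vol)[3]
  ii <- max(1, floor((y_um - lat_half_um) / px)):min(nr, ceiling((y_um + lat_half_um) / px))
  jj <- max(1, floor((x_um - lat_half_um) / px)):min(ncl, ceiling((x_um + lat_half_um) / px))
  yy <- (ii - 0.5) * px; xx <- (jj - 0.5) * px
  r <- sqrt(outer((yy - y_um)^2, (xx - x_um)^2, "+"))
  lat <- bead_lateral_profile(r, R, spec$lateral_sigma_um)
  for (k in seq_len(nz)) {
    dz <- (k - 0.5) * config$z_step_um - z_um
    w <- exp(-dz^2 / (2 * spec$axial_sigma_um^2))
    if (w > 1e-4) {
      vol[ii, jj, k] <- vol[ii, jj, k] + spec$peak_intensity * w * lat
    }
  }
  vol
}

#' Plant ground-truthed beads into a scene
#'
#' Samples bead centres uniformly inside the scene (with lateral margins so
#' the full blurred profile stays in frame, and axially within the sampled
#' plane range so every bead is imaged by at least two sections), enforces a
#' minimum lateral separation between distinct beads/clumps, and renders each
#' bead into the bead channel (channel 2) as a disk-times-Gaussian profile. A
#' fraction of beads is laid down in clumps of 2-3 with centres within one
#' bead diameter, mimicking the occasional bead clumps seen in tissue.
#'
#' @param scene a `bead_scene`.
#' @param n_beads number of bead centres to plant (total, including clump
#'   members).
#' @param spec a [bead_spec()].
#' @param clump_fraction fraction of beads belonging to clumps (default 0.05;
#'   fewer than 5 percent of beads in tissue are clumped).
#' @param seed integer seed.
#' @param min_separation_um minimum lateral centre separation between
#'   non-clumped beads (default 3, twice the upper detection diameter bound).
#' @return the scene with `n_beads` rows added to `truth` and the bead signal
#'   added to the bead channel.
#' @export
plant_beads <- function(scene, n_beads, spec = bead_spec(), clump_fraction = 0.05,
                        seed = 1, min_separation_um = 3) {
  if (!inherits(scene, "bead_scene")) stop("`scene` must be a bead_scene", call. = FALSE)
  if (n_beads < 0) stop("`n_beads` must be >= 0", call. = FALSE)
  if (clump_fraction < 0 || clump_fraction > 1) {
    stop("`clump_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (n_beads == 0) return(scene)
  cfg <- scene$config
  margin <- spec$diameter_um / 2 + 4 * spec$lateral_sigma_um
  if (cfg$width_um <= 2 * margin || cfg$height_um <= 2 * margin) {
    stop("scene too small to place beads", call. = FALSE)
  }
  zmin <- cfg$z_step_um / 2
  zmax <- cfg$nz * cfg$z_step_um - cfg$z_step_um / 2
  if (zmax < zmin) zmax <- zmin
  truth <- with_seed(seed, {
    # each bead is clumped with probability clump_fraction, so the realized
    # clump rate is unbiased at every plaque size
    n_clumped <- stats::rbinom(1, n_beads, clump_fraction)
    centers <- matrix(numeric(0), ncol = 3)
    clump_ids <- integer(0)
    placed_xy <- matrix(numeric(0), ncol = 2)
    next_clump <- 1L
    sample_primary <- function() {
      for (try in seq_len(2000L)) {
        x <- runif(1, margin, cfg$width_um - margin)
        y <- runif(1, margin, cfg$height_um - margin)
        if (nrow(placed_xy) == 0 ||
            min(sqrt((placed_xy[, 1] - x)^2 + (placed_xy[, 2] - y)^2)) >= min_separation_um) {
          return(c(x, y, runif(1, zmin, zmax)))
        }
      }
      stop("could not place beads at the requested density (scene too small)",
           call. = FALSE)
    }
    while (nrow(centers) < n_beads) {
      remaining <- n_beads - nrow(centers)
      remaining_clumped <- max(0L, n_clumped - sum(!is.na(clump_ids)))
      if (remaining_clumped >= 2L && remaining >= 2L) {
        size <- min(sample(2:3, 1), remaining_clumped, remaining)
        p <- sample_primary()
        placed_xy <- rbind(placed_xy, p[1:2])
        members <- p
        for (m in seq_len(size - 1L)) {
          ang <- runif(1, 0, 2 * pi)
          dd <- runif(1, 0.3 * spec$diameter_um, spec$diameter_um)
          dz <- runif(1, -spec$diameter_um / 2, spec$diameter_um / 2)
          members <- rbind(members, c(
            min(max(p[1] + dd * cos(ang), margin), cfg$width_um - margin),
            min(max(p[2] + dd * sin(ang), margin), cfg$height_um - margin),
            min(max(p[3] + dz, zmin), zmax)))
        }
        centers <- rbind(centers, members)
        clump_ids <- c(clump_ids, rep(next_clump, size))
        next_clump <- next_clump + 1L
      } else {
        p <- sample_primary()
        placed_xy <- rbind(placed_xy, p[1:2])
        centers <- rbind(centers, p)
        clump_ids <- c(clump_ids, NA_integer_)
      }
    }
    data.frame(x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
               clump_id = clump_ids)
  })
  ch <- bead_channel(scene$config)
  vol <- scene$volumes[[ch]]
  for (i in seq_len(nrow(truth))) {
    vol <- render_bead(vol, truth$x_um[i], truth$y_um[i], truth$z_um[i], spec, cfg)
  }
  scene$volumes[[ch]] <- vol
  scene$truth <- rbind(scene$truth, truth)
  rownames(scene$truth) <- NULL
  scene
}

# The band carrying the bead signal: the channel named green_490_530 if
# present, else the second channel.
bead_channel <- function(config) {
  i <- match("green_490_530", config$channels)
  if (is.na(i)) i <- min(2L, length(config$channels))
  config$channels[i]
}

#' Count axial sections in which each planted bead is visible
#'
#' For every ground-truth bead, counts the z-planes in which the bead-channel
#' intensity at the bead's lateral voxel exceeds `threshold`. On a noise-free,
#' zero-background scene this isolates the bead's own axial profile; with the
#' default bead spec and a 10 um axial step every bead is visible in at least
#' two sections.
#'
#' @param scene a `bead_scene` with planted beads.
#' @param threshold intensity threshold (default 10, the default detection
#'   threshold).
#' @return integer vector, one count per truth bead.
#' @export
bead_plane_visibility <- function(scene, threshold = 10) {
  cfg <- scene$config
  vol <- scene$volumes[[bead_channel(cfg)]]
  vapply(seq_len(nrow(scene$truth)), function(i) {
    j <- min(max(floor(scene$truth$x_um[i] / cfg$pixel_size_um) + 1L, 1L), cfg$nx)
    r <- min(max(floor(scene$truth$y_um[i] / cfg$pixel_size_um) + 1L, 1L), cfg$ny)
    sum(vol[r, j, ] > threshold)
  }, integer(1))
}
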