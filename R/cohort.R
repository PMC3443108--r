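#' Specification of a synthetic animal cohort
#'
#' Describes groups of animals with a mean planted bead count per plaque.
#' Effects between named groups may be given either directly through the
#' group means or as descriptors (`fold_ratio`, `reduction_percent`) that fill
#' in an `NA` group mean, mirroring the day-1 vs day-5 accumulation and the
#' statin-treatment experimental designs (5 and 3 mice per condition).
#'
#' @param groups data frame with columns `label`, `n_animals`, `mean_beads`
#'   (an `NA` mean is resolved from `effects`).
#' @param effects optional list of descriptors:
#'   `list(type = "fold_ratio", numerator =, denominator =, value =)` sets
#'   `mean(numerator) = value * mean(denominator)`;
#'   `list(type = "reduction_percent", treated =, control =, value =)` sets
#'   `mean(treated) = (1 - value/100) * mean(control)`.
#' @param seed integer seed governing all cohort randomness.
#' @param scene_config per-animal [scene_config()] (default: an 64x64x30 um
#'   field at 0.25 um/px).
#' @param bead_spec a [bead_spec()].
#' @param clump_fraction fraction of clumped beads per animal.
#' @param grid c(rows, cols) tiling grid per animal (default 2x2).
#' @param overlap_fraction tile overlap (default 0.1).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, effects = NULL, seed = 1,
                        scene_config = NULL, bead_spec = plaquebeads::bead_spec(),
                        clump_fraction = 0.05, grid = c(2, 2),
                        overlap_fraction = 0.1) {
  groups <- as.data.frame(groups)
  if (!all(c("label", "n_animals", "mean_beads") %in% names(groups))) {
    stop("`groups` needs columns label, n_animals, mean_beads", call. = FALSE)
  }
  if (any(groups$n_animals < 1)) stop("n_animals must be >= 1", call. = FALSE)
  for (eff in effects) {
    refs <- switch(eff$type,
                   fold_ratio = c(eff$numerator, eff$denominator),
                   reduction_percent = c(eff$treated, eff$control),
                   stop("unknown effect type: ", eff$type, call. = FALSE))
    if (!all(refs %in% groups$label)) {
      stop("effect references unknown group label(s): ",
           paste(setdiff(refs, groups$label), collapse = ", "), call. = FALSE)
    }
    if (eff$type == "fold_ratio" && is.na(groups$mean_beads[groups$label == eff$numerator])) {
      groups$mean_beads[groups$label == eff$numerator] <-
        eff$value * groups$mean_beads[groups$label == eff$denominator]
    }
    if (eff$type == "reduction_percent" && is.na(groups$mean_beads[groups$label == eff$treated])) {
      groups$mean_beads[groups$label == eff$treated] <-
        (1 - eff$value / 100) * groups$mean_beads[groups$label == eff$control]
    }
  }
  if (any(is.na(groups$mean_beads)) || any(groups$mean_beads < 0)) {
    stop("all group means must resolve to non-negative values", call. = FALSE)
  }
  if (is.null(scene_config)) {
    scene_config <- plaquebeads::scene_config(width_um = 64, height_um = 64, depth_um = 30)
  }
  structure(list(groups = groups, effects = effects, seed = seed,
                 scene_config = scene_config, bead_spec = bead_spec,
                 clump_fraction = clump_fraction, grid = grid,
                 overlap_fraction = overlap_fraction),
            class = "cohort_spec")
}

#' Generate a cohort of tiled synthetic plaque acquisitions
#'
#' For each animal, draws a planted bead count from a Poisson distribution
#' around its group mean, renders a seeded scene with that many beads, and
#' tiles it with overlap. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list of animals, each `list(group, animal_id, tiles, truth)` where
#'   `tiles` is a `tile_set` and `truth` its planted ground truth.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  plan <- with_seed(spec$seed, {
    rows <- list()
    for (g in seq_len(nrow(spec$groups))) {
      for (a in seq_len(spec$groups$n_animals[g])) {
        rows[[length(rows) + 1L]] <- list(
          group = spec$groups$label[g],
          animal_id = sprintf("%s_%02d", spec$groups$label[g], a),
          n_beads = stats::rpois(1, spec$groups$mean_beads[g]),
          scene_seed = sample.int(.Machine$integer.max - 1L, 1),
          bead_seed = sample.int(.Machine$integer.max - 1L, 1))
      }
    }
    rows
  })
  lapply(plan, function(p) {
    scene <- generate_scene(spec$scene_config, seed = p$scene_seed)
    scene <- plant_beads(scene, p$n_beads, spec$bead_spec,
                         clump_fraction = spec$clump_fraction, seed = p$bead_seed)
    tiles <- tile_scene(scene, spec$grid[1], spec$grid[2], spec$overlap_fraction)
    list(group = p$group, animal_id = p$animal_id, tiles = tiles,
         truth = scene$truth)
  })
}

#' Count beads for every animal of a generated cohort
#'
#' Applies the end-to-end [count_sample()] pipeline per animal.
#'
#' @param cohort output of [generate_cohort()].
#' @param params a [detection_params()].
#' @return data frame with columns `group`, `animal_id`, `count`,
#'   `truth_count`.
#' @export
count_cohort <- function(cohort, params = detection_params()) {
  do.call(rbind, lapply(cohort, function(an) {
    data.frame(group = an$group, animal_id = an$animal_id,
               count = count_sample(an$tiles, params),
               truth_count = nrow(an$truth))
  }))
}
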