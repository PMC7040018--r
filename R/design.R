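#' Study design for a synthetic droplet experiment
#'
#' Describes the layout of a droplet imaging study: how many participants,
#' which ordered physiological conditions, how many replicate droplet images
#' per (participant, condition) cell, and the raster geometry.  The defaults
#' mirror the cohort the discrimination method was developed on: 30
#' participants sampled at baseline, at peak exertion and at 2, 4 and 6
#' minutes of recovery, with 10-12 droplet images per cell.
#'
#' @param n_participants number of participants (>= 2).
#' @param conditions ordered character vector of condition labels.
#' @param images_per_cell replicate images per cell; either a single count or
#'   a length-2 inclusive range from which each cell's count is drawn.
#' @param image_size_px edge length of the square image raster.
#' @param droplet_radius_px droplet radius in pixels; the droplet must fit in
#'   the image with at least a 5 px margin.
#' @param pixel_pitch nominal resolution in pixels per mm.
#' @param master_seed integer seed from which all per-cell seeds derive.
#' @return an object of class `dd_design`.
#' @export
study_design <- function(n_participants = 30,
                         conditions = c("baseline", "peak", "rec2", "rec4", "rec6"),
                         images_per_cell = c(10, 12),
                         image_size_px = 160,
                         droplet_radius_px = 64,
                         pixel_pitch = 150,
                         master_seed = 1L) {
  stop_if_not(n_participants >= 2, "n_participants must be >= 2, got %s", n_participants)
  stop_if_not(length(conditions) >= 1 && !anyDuplicated(conditions),
              "conditions must be a non-empty list of distinct labels")
  if (length(images_per_cell) == 1) images_per_cell <- rep(images_per_cell, 2)
  stop_if_not(length(images_per_cell) == 2 && images_per_cell[1] >= 1 &&
                images_per_cell[2] >= images_per_cell[1],
              "images_per_cell must be a count or increasing range >= 1")
  stop_if_not(image_size_px / 2 >= droplet_radius_px + 5,
              "droplet (radius %d) does not fit in a %d px image with a 5 px margin",
              droplet_radius_px, image_size_px)
  structure(
    list(n_participants = as.integer(n_participants),
         conditions = as.character(conditions),
         images_per_cell = as.integer(images_per_cell),
         image_size_px = as.integer(image_size_px),
         droplet_radius_px = as.integer(droplet_radius_px),
         pixel_pitch = pixel_pitch,
         master_seed = as.integer(master_seed)),
    class = "dd_design")
}

#' Droplet phenotype
#'
#' Morphological parameters of one rendered droplet: a red-dominated circular
#' deposit with a darker peripheral rim, radial cracks in the corona,
#' disordered short cracks in the centre, and a condition-dependent angular
#' intensity texture with `angular_mode` repetitions per revolution.
#'
#' @param n_radial_cracks number of radial corona cracks.
#' @param central_crack_density short central cracks per px^2 of central zone.
#' @param rim_width_frac rim annulus width as a fraction of the radius, in (0, 0.5).
#' @param rim_darkening multiplicative intensity factor applied in the rim, in (0, 1].
#' @param angular_mode dominant angular frequency of the corona texture,
#'   in cycles per revolution; must stay below half the angular sample count
#'   of the downstream polar grid.
#' @param texture_amp relative amplitude of the angular intensity modulation.
#' @param noise_sd additive Gaussian pixel noise, 8-bit intensity units.
#' @return an object of class `dd_phenotype`.
#' @export
droplet_phenotype <- function(n_radial_cracks = 16,
                              central_crack_density = 0.004,
                              rim_width_frac = 0.12,
                              rim_darkening = 0.65,
                              angular_mode = 4,
                              texture_amp = 0.15,
                              noise_sd = 2) {
  check_range <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
    bad <- !is.finite(x) ||
      (if (lo_open) x <= lo else x < lo) ||
      (if (hi_open) x >= hi else x > hi)
    stop_if_not(!bad, "phenotype parameter '%s' out of range: %s", name, format(x))
  }
  check_range(n_radial_cracks, 0, Inf, "n_radial_cracks")
  check_range(central_crack_density, 0, Inf, "central_crack_density")
  check_range(rim_width_frac, 0, 0.5, "rim_width_frac", lo_open = TRUE, hi_open = TRUE)
  check_range(rim_darkening, 0, 1, "rim_darkening", lo_open = TRUE)
  check_range(angular_mode, 0, Inf, "angular_mode")
  check_range(texture_amp, 0, 1, "texture_amp")
  check_range(noise_sd, 0, Inf, "noise_sd")
  structure(
    list(n_radial_cracks = as.integer(round(n_radial_cracks)),
         central_crack_density = central_crack_density,
         rim_width_frac = rim_width_frac,
         rim_darkening = rim_darkening,
         angular_mode = as.integer(round(angular_mode)),
         texture_amp = texture_amp,
         noise_sd = noise_sd),
    class = "dd_phenotype")
}

## Apply a named list of additive offsets to a phenotype, re-validating.
shift_phenotype <- function(phenotype, offsets) {
  if (length(offsets) == 0) return(phenotype)
  p <- unclass(phenotype)
  for (nm in names(offsets)) {
    stop_if_not(nm %in% names(p), "unknown phenotype field '%s'", nm)
    p[[nm]] <- p[[nm]] + offsets[[nm]]
  }
  ## clamp fields that jitter could push marginally out of range
  p$n_radial_cracks <- max(0, p$n_radial_cracks)
  p$central_crack_density <- max(0, p$central_crack_density)
  p$rim_darkening <- min(1, max(1e-3, p$rim_darkening))
  p$rim_width_frac <- min(0.49, max(1e-3, p$rim_width_frac))
  p$angular_mode <- max(0, p$angular_mode)
  p$noise_sd <- max(0, p$noise_sd)
  do.call(droplet_phenotype, p)
}

#' Per-condition phenotype offsets
#'
#' Build the mapping from condition label to phenotype offset that carries
#' the class signal of a synthetic study.  Offsets are added to the base
#' phenotype.  `null_effect()` gives the zero-effect (chance-level) study.
#'
#' @param conditions ordered condition labels.
#' @param angular_mode,n_radial_cracks per-condition additive offsets,
#'   recycled to `length(conditions)`.
#' @return named list of per-condition offset lists.
#' @export
graded_effect <- function(conditions, angular_mode = 0, n_radial_cracks = 0) {
  am <- rep_len(angular_mode, length(conditions))
  nc <- rep_len(n_radial_cracks, length(conditions))
  eff <- lapply(seq_along(conditions), function(i) {
    list(angular_mode = am[i], n_radial_cracks = nc[i])
  })
  names(eff) <- conditions
  eff
}

#' @rdname graded_effect
#' @export
null_effect <- function(conditions) {
  graded_effect(conditions, angular_mode = 0, n_radial_cracks = 0)
}
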