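#' Render one synthetic dried droplet image
#'
#' Draws a single circular blood deposit on a uniform pale background:
#' a red-dominated body whose red channel carries an angular cosine texture
#' at `angular_mode` cycles per revolution, a darker peripheral rim,
#' `n_radial_cracks` near-white radial cracks in the corona, disordered short
#' white cracks in the central zone, and additive Gaussian pixel noise.
#' All angular structure (texture phase, crack positions) is shifted by
#' `rotation`, so two renders differing only in `rotation` are rotations of
#' one another in the continuous domain.  The output is deterministic given
#' `seed`; the same random draws are made whatever the value of `rotation`.
#'
#' @param design a [study_design()].
#' @param phenotype a [droplet_phenotype()].
#' @param rotation rotation angle in radians, applied to all angular structure.
#' @param seed integer RNG seed for this image.
#' @return integer array `c(n, n, 3)` (R, G, B in 0..255) with attributes
#'   `crack_mask` (logical ground-truth crack raster), `centre`, `radius`
#'   and `pixel_pitch`.
#' @export
generate_droplet_image <- function(design, phenotype, rotation = 0, seed = 1L) {
  stopifnot(inherits(design, "dd_design"), inherits(phenotype, "dd_phenotype"))
  n <- design$image_size_px
  R <- design$droplet_radius_px
  c0 <- (n + 1) / 2
  ph <- phenotype

  ## polar coordinates of every pixel about the droplet centre
  d <- (1:n) - c0
  dy <- matrix(d, n, n)          # row offsets
  dx <- matrix(d, n, n, byrow = TRUE)  # col offsets
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)

  bg <- 185
  red <- matrix(bg, n, n)
  grn <- matrix(bg, n, n)
  blu <- matrix(bg, n, n)

  inside <- r <= R
  rim_r0 <- R * (1 - ph$rim_width_frac)
  corona <- inside & r >= 0.45 * R

  ## deposit body: red channel high relative to green/blue, mildly darker
  ## towards the rim; angular texture modulates the corona
  body_red <- 150 - 20 * (r / R)
  tex <- 1 + ph$texture_amp * cos(ph$angular_mode * (th - rotation))
  body_red[corona] <- body_red[corona] * tex[corona]
  rim <- inside & r > rim_r0
  rim_tex <- ph$rim_darkening * (1 + 0.5 * ph$texture_amp *
                                   cos(ph$angular_mode * (th - rotation)))
  body_red[rim] <- body_red[rim] * rim_tex[rim]
  red[inside] <- body_red[inside]
  grn[inside] <- 60 * ifelse(rim[inside], ph$rim_darkening, 1)
  blu[inside] <- 55 * ifelse(rim[inside], ph$rim_darkening, 1)

  ## cracks: near-white thin polylines; ground truth raster retained
  crack <- matrix(FALSE, n, n)
  mark_segment <- function(mask, r0, th0, r1, th1) {
    ## polar endpoints -> dense cartesian samples, 1-2 px wide
    x0 <- r0 * cos(th0); y0 <- r0 * sin(th0)
    x1 <- r1 * cos(th1); y1 <- r1 * sin(th1)
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4)))
    xs <- x0 + t * (x1 - x0)
    ys <- y0 + t * (y1 - y0)
    ## thickness: the pixel itself plus a half-pixel perpendicular offset
    nxp <- -(y1 - y0) / max(len, 1e-9)
    nyp <- (x1 - x0) / max(len, 1e-9)
    rows <- round(c0 + c(ys, ys + 0.5 * nyp))
    cols <- round(c0 + c(xs, xs + 0.5 * nxp))
    ok <- rows >= 1 & rows <= n & cols >= 1 & cols <= n
    mask[cbind(rows[ok], cols[ok])] <- TRUE
    mask
  }

  img <- withr::with_seed(as.integer(seed), {
    ## draw all randomness first, then apply `rotation`, so the same seed
    ## yields the same droplet at every rotation
    k <- ph$n_radial_cracks
    if (k > 0) {
      jit <- stats::rnorm(k, 0, 0.04)
      r_in <- stats::runif(k, 0.45, 0.55) * R
      phi <- 2 * pi * (0:(k - 1)) / k + jit
      for (i in seq_len(k)) {
        crack <- mark_segment(crack, r_in[i], phi[i] + rotation,
                              rim_r0, phi[i] + rotation)
      }
    }
    n_cen <- round(ph$central_crack_density * pi * (0.45 * R)^2)
    if (n_cen > 0) {
      rc <- sqrt(stats::runif(n_cen)) * 0.4 * R
      ac <- stats::runif(n_cen, 0, 2 * pi)
      ln <- stats::runif(n_cen, 4, 12)
      dir <- stats::runif(n_cen, 0, 2 * pi)
      for (i in seq_len(n_cen)) {
        x0 <- rc[i] * cos(ac[i] + rotation)
        y0 <- rc[i] * sin(ac[i] + rotation)
        x1 <- x0 + ln[i] * cos(dir[i] + rotation)
        y1 <- y0 + ln[i] * sin(dir[i] + rotation)
        r1 <- sqrt(x1^2 + y1^2)
        crack <- mark_segment(crack, rc[i], ac[i] + rotation,
                              r1, atan2(y1, x1))
      }
    }
    crack <- crack & inside
    red[crack] <- 250
    grn[crack] <- 250
    blu[crack] <- 250

    arr <- array(0, dim = c(n, n, 3))
    arr[, , 1] <- red
    arr[, , 2] <- grn
    arr[, , 3] <- blu
    if (ph$noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, ph$noise_sd)
    }
    arr
  })

  out <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim = c(n, n, 3))
  attr(out, "crack_mask") <- crack
  attr(out, "centre") <- c(c0, c0)
  attr(out, "radius") <- R
  attr(out, "pixel_pitch") <- design$pixel_pitch
  out
}

#' Generate a labelled synthetic droplet study
#'
#' Builds the manifest of a full (participant x condition x replicate) study.
#' Each participant receives a random phenotype offset (shared across their
#' conditions, modelling stable individual morphology); each condition adds
#' its `class_effect` offset; each replicate image gets its own seed and a
#' uniform random orientation.  Images are rendered lazily with
#' [study_image()] so large studies need not be held in memory.
#'
#' @param design a [study_design()].
#' @param class_effect named per-condition offset list, e.g. from
#'   [graded_effect()]; must cover every condition of the design.
#' @param base_phenotype the phenotype the offsets apply to.
#' @param participant_sd named list of per-participant offset standard
#'   deviations (integer-valued fields are rounded after drawing).
#' @param replicate_sd named list of per-image offset standard deviations:
#'   droplets pipetted from the same blood sample still dry into visibly
#'   different patterns, which is what makes replicate averaging worthwhile.
#' @return an object of class `dd_study`: the design, a manifest data frame
#'   (participant, condition, replicate, seed, rotation and the per-image
#'   phenotype parameters) and the per-participant offsets.
#' @export
generate_study <- function(design,
                           class_effect = null_effect(design$conditions),
                           base_phenotype = droplet_phenotype(),
                           participant_sd = list(angular_mode = 0.5,
                                                 n_radial_cracks = 1,
                                                 rim_darkening = 0.03),
                           replicate_sd = list(angular_mode = 1,
                                               n_radial_cracks = 2,
                                               texture_amp = 0.03)) {
  stopifnot(inherits(design, "dd_design"))
  stop_if_not(length(design$conditions) >= 1, "empty conditions list")
  stop_if_not(all(design$conditions %in% names(class_effect)),
              "class_effect must map every condition of the design")

  int_fields <- c("angular_mode", "n_radial_cracks")
  p_off <- withr::with_seed(cell_seed(design$master_seed, 0L, 0L, 0L), {
    lapply(seq_len(design$n_participants), function(p) {
      off <- lapply(participant_sd, function(s) stats::rnorm(1, 0, s))
      for (nm in intersect(names(off), int_fields)) off[[nm]] <- round(off[[nm]])
      off
    })
  })

  rows <- list()
  for (p in seq_len(design$n_participants)) {
    for (ci in seq_along(design$conditions)) {
      cond <- design$conditions[ci]
      n_rep <- if (design$images_per_cell[1] == design$images_per_cell[2]) {
        design$images_per_cell[1]
      } else {
        withr::with_seed(cell_seed(design$master_seed, p, ci, 0L),
                         sample(design$images_per_cell[1]:design$images_per_cell[2], 1))
      }
      ph <- shift_phenotype(base_phenotype, class_effect[[cond]])
      ph <- shift_phenotype(ph, p_off[[p]])
      for (k in seq_len(n_rep)) {
        sd_k <- cell_seed(design$master_seed, p, ci, k)
        draws <- withr::with_seed(sd_k, {
          rot <- stats::runif(1, 0, 2 * pi)
          off <- lapply(replicate_sd, function(s) stats::rnorm(1, 0, s))
          list(rot = rot, off = off)
        })
        for (nm in intersect(names(draws$off), int_fields)) {
          draws$off[[nm]] <- round(draws$off[[nm]])
        }
        ph_k <- shift_phenotype(ph, draws$off)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, condition = cond, replicate = k,
          seed = sd_k, rotation = draws$rot,
          n_radial_cracks = ph_k$n_radial_cracks,
          central_crack_density = ph_k$central_crack_density,
          rim_width_frac = ph_k$rim_width_frac,
          rim_darkening = ph_k$rim_darkening,
          angular_mode = ph_k$angular_mode,
          texture_amp = ph_k$texture_amp,
          noise_sd = ph_k$noise_sd,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(design = design, manifest = manifest,
                 participant_offsets = p_off, class_effect = class_effect),
            class = "dd_study")
}

#' Render one image of a study
#'
#' @param study a `dd_study` from [generate_study()].
#' @param i manifest row index.
#' @return the rendered image (see [generate_droplet_image()]).
#' @export
study_image <- function(study, i) {
  stopifnot(inherits(study, "dd_study"))
  m <- study$manifest[i, ]
  ph <- droplet_phenotype(
    n_radial_cracks = m$n_radial_cracks,
    central_crack_density = m$central_crack_density,
    rim_width_frac = m$rim_width_frac,
    rim_darkening = m$rim_darkening,
    angular_mode = m$angular_mode,
    texture_amp = m$texture_amp,
    noise_sd = m$noise_sd)
  generate_droplet_image(study$design, ph, rotation = m$rotation, seed = m$seed)
}

#' Write a study to disk as PNG images plus a manifest
#'
#' Lays the images out as `participant_<i>/<condition>/img_<k>.png` under
#' `dir` and writes `manifest.csv` with one row per image (path, seed and
#' phenotype parameters included).
#'
#' @param study a `dd_study`.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest with a `path` column.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dd_study"))
  m <- study$manifest
  m$path <- file.path(sprintf("participant_%02d", m$participant),
                      m$condition, sprintf("img_%02d.png", m$replicate))
  for (i in seq_len(nrow(m))) {
    f <- file.path(dir, m$path[i])
    dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
    img <- study_image(study, i)
    png::writePNG(array(img / 255, dim = dim(img)), target = f)
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}

#' Read an RGB droplet image from a PNG file
#'
#' @param path PNG file with at least three channels.
#' @return integer array `c(h, w, 3)` with intensities 0..255.
#' @export
read_droplet_png <- function(path) {
  a <- png::readPNG(path)
  stop_if_not(length(dim(a)) == 3 && dim(a)[3] >= 3,
              "expected a 3-channel image: %s", path)
  array(as.integer(round(a[, , 1:3] * 255)), dim = c(dim(a)[1], dim(a)[2], 3))
}
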