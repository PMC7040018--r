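#' Locate the droplet centre and radius
#'
#' Lightly smooths the channel, thresholds it with Otsu's method (the
#' deposit is darker than the pale backlit background), keeps the largest
#' connected component, fills its holes (cracks punch holes in the raw
#' mask), and reports the component centroid and the equivalent-area radius
#' `sqrt(area / pi)`.
#'
#' @param ch numeric matrix (red channel, cracks filled or not).
#' @param smooth_sigma Gaussian width (cycles/pixel) of the pre-threshold
#'   smoothing.
#' @param min_area_frac smallest acceptable component area as a fraction of
#'   the image; below this the image is considered to contain no deposit.
#' @return list with `centre` (row, col) and `radius` in pixels.
#' @export
find_centre <- function(ch, smooth_sigma = 0.15, min_area_frac = 0.01) {
  stop_if_not(is.matrix(ch) && all(is.finite(ch)), "input must be a finite matrix")
  sm <- gaussian_lowpass(ch, smooth_sigma)
  rng <- range(sm)
  stop_if_not(diff(rng) > 1e-8, "image is constant: no deposit found")
  v <- (sm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(v))
  mask <- v < th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  stop_if_not(max(lab) >= 1, "no deposit component found")
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  stop_if_not(areas[big] >= min_area_frac * length(ch),
              "largest component covers %.2f%% of the image (< %.0f%%): no deposit",
              100 * areas[big] / length(ch), 100 * min_area_frac)
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image((lab == big) * 1))) > 0
  idx <- which(comp, arr.ind = TRUE)
  list(centre = colMeans(idx)[c("row", "col")],
       radius = sqrt(nrow(idx) / pi))
}

#' Resample a channel image on a polar grid
#'
#' Bilinearly samples the image at `n_r` radii `r_i = i * radius / n_r`
#' (i = 1..n_r, spanning (0, radius]) and `n_theta` uniformly spaced angles
#' `theta_j = theta0 + 2 pi j / n_theta` about `centre`; row offsets follow
#' `sin(theta)`, column offsets `cos(theta)`.  Samples falling outside the
#' raster take the clamped border value.  `theta0` rotates the sampling
#' frame: an offset of `2 pi k / n_theta` reproduces exactly the sample set
#' of the image rotated by that angle about the centre, with no
#' interpolation loss.
#'
#' @param ch numeric matrix.
#' @param centre (row, col) of the droplet centre.
#' @param radius droplet radius in pixels; must exceed `n_r` so each radial
#'   bin spans at least one pixel.
#' @param n_r,n_theta polar grid size (defaults 48 x 103).
#' @param theta0 angular origin of the sampling frame, radians.
#' @return `n_r x n_theta` matrix of class `dd_polar` with attributes
#'   `centre`, `radius`, `theta0`.
#' @export
to_polar <- function(ch, centre, radius, n_r = 48, n_theta = 103, theta0 = 0) {
  stop_if_not(radius > 0, "radius must be positive")
  stop_if_not(n_r >= 2 && n_theta >= 4, "polar grid too small")
  stop_if_not(radius > n_r,
              "radius (%.1f px) must exceed n_r (%d): at least 1 px per radial bin",
              radius, n_r)
  r <- (1:n_r) * radius / n_r
  th <- theta0 + 2 * pi * (0:(n_theta - 1)) / n_theta
  rows <- centre[1] + outer(r, sin(th))
  cols <- centre[2] + outer(r, cos(th))
  pol <- matrix(bilinear_sample(ch, rows, cols), n_r, n_theta)
  structure(pol, class = c("dd_polar", "matrix", "array"),
            centre = centre, radius = radius, theta0 = theta0)
}

#' Rotate an image about a point
#'
#' Inverse-mapped bilinear rotation of a single channel or an RGB array
#' about `centre`.  Pixels mapping outside the source raster take the
#' clamped border value.  Raster rotation is lossy (interpolation error of
#' order 1% on droplet textures); rotations by multiples of the polar grid
#' spacing are better represented exactly via the `theta0` argument of
#' [to_polar()].
#'
#' @param img matrix or `c(h, w, 3)` array.
#' @param angle rotation angle in radians (anticlockwise in (row, col)
#'   convention matching [to_polar()]).
#' @param centre (row, col) rotation centre; defaults to the image midpoint.
#' @return rotated image of the same shape and type (numeric).
#' @export
rotate_image <- function(img, angle, centre = NULL) {
  rot_one <- function(ch) {
    nr <- nrow(ch); nc <- ncol(ch)
    c0 <- centre %||% c((nr + 1) / 2, (nc + 1) / 2)
    g_r <- matrix(1:nr, nr, nc) - c0[1]
    g_c <- matrix(1:nc, nr, nc, byrow = TRUE) - c0[2]
    ## inverse map: source = R(-angle) %*% target
    src_r <- c0[1] + cos(angle) * g_r - sin(angle) * g_c
    src_c <- c0[2] + sin(angle) * g_r + cos(angle) * g_c
    matrix(bilinear_sample(ch, src_r, src_c), nr, nc)
  }
  if (length(dim(img)) == 3) {
    out <- array(0, dim = dim(img))
    for (k in seq_len(dim(img)[3])) out[, , k] <- rot_one(matrix(as.numeric(img[, , k]), dim(img)[1]))
    out
  } else {
    rot_one(img)
  }
}

#' Angular log power spectrum of a polar image
#'
#' Per radial row: take `log(value + eps)`, Fourier-transform along the
#' angle, take the magnitude, then `log(magnitude + eps)` again.  The
#' magnitude discards all phase, so the result is invariant to circular
#' shifts along the angle — i.e. to rotations of the droplet about its
#' centre.  Frequencies are indexed 0..n_theta-1 in cycles per revolution.
#'
#' @param pol polar image from [to_polar()] (values must be non-negative,
#'   as produced by [laplacian_magnitude()]).
#' @param eps additive floor inside both logarithms (the spectrum and the
#'   Laplacian magnitude can both reach exact zeros).
#' @return object of class `dd_spectrum`: list with `gamma`
#'   (`n_r x n_theta` log-power matrix), `eps`, `n_r`, `n_theta`.
#' @export
log_power_spectrum <- function(pol, eps = 1e-6) {
  stop_if_not(all(pol >= 0), "polar values must be non-negative")
  stop_if_not(eps > 0, "eps must be positive")
  L <- log(unclass(pol) + eps)
  ## FFT along the angular coordinate of every radial row
  Fmag <- abs(t(stats::mvfft(t(L))))
  structure(list(gamma = log(Fmag + eps), eps = eps,
                 n_r = nrow(L), n_theta = ncol(L)),
            class = "dd_spectrum")
}

#' Truncate a spectral matrix to the informative block
#'
#' Drops the first radial row (the innermost ring carries negligible radial
#' information) and keeps only the first half of the frequency bandwidth
#' (the magnitude spectrum of a real signal is symmetric, and the upper
#' half adds little).  At the default 48 x 103 grid this leaves 47 rows and
#' 52 frequency columns, flattened row-major into a 2444-long vector.
#'
#' @param sf a `dd_spectrum` (or its `gamma` matrix).
#' @return numeric feature vector of length `(n_r - 1) * ceiling(n_theta / 2)`
#'   with attributes `n_rows`, `n_cols`.
#' @export
truncate_features <- function(sf) {
  g <- if (inherits(sf, "dd_spectrum")) sf$gamma else sf
  stop_if_not(is.matrix(g) && nrow(g) >= 2 && ncol(g) >= 2,
              "expected a spectral matrix with >= 2 rows and columns")
  n_cols <- ceiling(ncol(g) / 2)
  block <- g[-1, seq_len(n_cols), drop = FALSE]
  v <- as.vector(t(block))    # row-major: all frequencies of row 2, then row 3, ...
  attr(v, "n_rows") <- nrow(block)
  attr(v, "n_cols") <- n_cols
  v
}

#' Image to feature vector
#'
#' The full chain from an RGB droplet photograph to the rotation-invariant
#' spectral feature vector: [preprocess_image()], [find_centre()],
#' [to_polar()], [log_power_spectrum()], [truncate_features()].
#'
#' @param img RGB array.
#' @param alpha,sigma pre-processing parameters.
#' @param n_r,n_theta polar grid (48 x 103 yields the standard 2444-vector).
#' @param eps log floor of [log_power_spectrum()].
#' @param theta0 angular origin of the polar sampling frame.
#' @param centre_sigma smoothing width used by [find_centre()].
#' @return feature vector (length `(n_r - 1) * ceiling(n_theta / 2)`) with
#'   attributes `centre` and `radius`.
#' @export
image_features <- function(img, alpha = 200, sigma = 0.01,
                           n_r = 48, n_theta = 103, eps = 1e-6,
                           theta0 = 0, centre_sigma = 0.15) {
  pre <- preprocess_image(img, alpha = alpha, sigma = sigma)
  cen <- find_centre(pre$filled, smooth_sigma = centre_sigma)
  pol <- to_polar(pre$laplacian, cen$centre, cen$radius,
                  n_r = n_r, n_theta = n_theta, theta0 = theta0)
  v <- truncate_features(log_power_spectrum(pol, eps = eps))
  attr(v, "centre") <- cen$centre
  attr(v, "radius") <- cen$radius
  v
}

#' Average replicate feature vectors and min-max normalise
#'
#' Averages the first `k` replicate vectors of one (participant, condition)
#' cell — replicates in manifest (acquisition) order — then rescales the
#' averaged vector to span [0, 1] exactly.  A constant vector (max equals
#' min) is mapped to all zeros with a warning.
#'
#' @param vectors matrix with one replicate vector per column (or a list of
#'   vectors).
#' @param k number of replicates to average, `1 <= k <=` available; or
#'   `"all"`.
#' @return normalised feature vector.
#' @export
average_and_normalise <- function(vectors, k = "all") {
  m <- if (is.list(vectors)) do.call(cbind, vectors) else as.matrix(vectors)
  n_rep <- ncol(m)
  if (identical(k, "all")) k <- n_rep
  stop_if_not(is.numeric(k) && k >= 1 && k <= n_rep,
              "k must lie in 1..%d (or \"all\"), got %s", n_rep, format(k))
  v <- rowMeans(m[, seq_len(k), drop = FALSE])
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant feature vector: min-max normalisation returns all zeros")
    return(rep(0, length(v)))
  }
  (v - rng[1]) / diff(rng)
}

#' Assemble a condition matrix
#'
#' One min-max-normalised, k-averaged feature column per participant for a
#' single condition.
#'
#' @param cell_vectors named list (by participant) of replicate matrices,
#'   as produced by [study_feature_vectors()] for one condition.
#' @param k replicates to average (see [average_and_normalise()]).
#' @return feature matrix (features x participants) of class `dd_condmat`.
#' @export
condition_matrix <- function(cell_vectors, k = "all") {
  cols <- lapply(cell_vectors, average_and_normalise, k = k)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cell_vectors)
  structure(m, class = c("dd_condmat", "matrix", "array"), k = k)
}
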