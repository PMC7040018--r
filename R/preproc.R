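#' Red channel of an RGB image
#'
#' The informative droplet structure sits almost entirely in the red channel
#' of a backlit blood droplet photograph; the whole pipeline operates on it.
#'
#' @param img integer or numeric array `c(h, w, 3)`.
#' @return numeric matrix `h x w`.
#' @export
red_channel <- function(img) {
  stop_if_not(length(dim(img)) == 3 && dim(img)[3] == 3,
              "expected a 3-channel image, got %s channels",
              if (length(dim(img)) == 3) dim(img)[3] else "a non-3D array")
  matrix(as.numeric(img[, , 1]), dim(img)[1], dim(img)[2])
}

#' Detect crack pixels
#'
#' Cracks in the dried deposit transmit the backlight and appear as
#' near-white pixels.  A pixel is flagged as crack exactly where both the
#' blue and the green channel exceed `alpha`; the red-dominated deposit body
#' (green/blue low) never triggers the criterion.
#'
#' @param img RGB array `c(h, w, 3)`.
#' @param alpha intensity threshold in (0, 255); the default of 200 catches
#'   rendered cracks (~250) while sparing deposit and pale background.
#' @return logical matrix, `TRUE` at crack pixels.
#' @export
detect_cracks <- function(img, alpha = 200) {
  stop_if_not(length(dim(img)) == 3 && dim(img)[3] == 3, "expected a 3-channel image")
  stop_if_not(alpha > 0 && alpha < 255, "alpha must lie in (0, 255), got %s", alpha)
  img[, , 2] > alpha & img[, , 3] > alpha
}

#' Fill (inpaint) crack pixels
#'
#' Replaces masked pixels by the discrete harmonic interpolant of the
#' surrounding unmasked values: the masked set is solved as a Laplace
#' equation with Dirichlet data on its unmasked neighbours (sparse direct
#' solve).  Unmasked pixels are returned unchanged.  The interpolant
#' reproduces any affine intensity field exactly on interior masks and
#' extends naturally to masked pixels at the image border (where scattered
#' triangulation-based schemes leave a convex-hull gap).  Filling is
#' idempotent for a fixed mask.
#'
#' @param ch numeric matrix (e.g. the red channel).
#' @param mask logical matrix of the same shape, `TRUE` where to fill.
#' @return matrix of the same shape with masked pixels interpolated.
#' @export
fill_cracks <- function(ch, mask) {
  stop_if_not(is.matrix(ch) && all(dim(ch) == dim(mask)),
              "image and mask shapes differ")
  if (!any(mask)) return(ch)
  stop_if_not(sum(!mask) >= 3, "mask covers (almost) the whole image")

  nr <- nrow(ch)
  nc <- ncol(ch)
  idx <- which(mask)                      # linear indices of unknowns
  pos <- match(seq_len(nr * nc), idx)     # pixel -> unknown number (NA if known)

  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(length(idx))
  deg <- numeric(length(idx))
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nbr_r <- rows + d[1]
    nbr_c <- cols + d[2]
    ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= nc
    nb_lin <- (nbr_c[ok] - 1) * nr + nbr_r[ok]
    u <- which(ok)
    deg[u] <- deg[u] + 1
    nb_pos <- pos[nb_lin]
    known <- is.na(nb_pos)
    b[u[known]] <- b[u[known]] + ch[nb_lin[known]]
    ii <- c(ii, u[!known])
    jj <- c(jj, nb_pos[!known])
    xx <- c(xx, rep(-1, sum(!known)))
  }
  A <- Matrix::sparseMatrix(i = c(seq_along(idx), ii), j = c(seq_along(idx), jj),
                            x = c(deg, xx), dims = c(length(idx), length(idx)))
  sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                  error = function(e) {
                    ## a masked component sealed off from all unmasked pixels
                    rep(mean(ch[!mask]), length(idx))
                  })
  out <- ch
  out[idx] <- sol
  out
}

#' Fourier-domain Gaussian low-pass filter
#'
#' Multiplies the 2D DFT of the image by `G(u, v) = exp(-(u^2 + v^2) /
#' sigma^2)` evaluated on the centred frequency grid in cycles per pixel,
#' then inverse-transforms and keeps the real part.  The DC weight is
#' exactly 1, so the image mean is preserved; for very large `sigma` the
#' filter tends to the identity.  Note the transfer function carries no
#' factor 2 in the denominator: `sigma` is the e^-1 half-width of the
#' squared-frequency roll-off.
#'
#' @param ch numeric matrix.
#' @param sigma filter width in cycles per pixel (> 0); default 0.01,
#'   appropriate for ~300 px-radius droplets (see [scaled_sigma()] for other
#'   scales).
#' @return filtered matrix, same shape.
#' @export
gaussian_lowpass <- function(ch, sigma = 0.01) {
  stop_if_not(is.matrix(ch) && all(is.finite(ch)), "input must be a finite matrix")
  stop_if_not(is.finite(sigma) && sigma > 0, "sigma must be positive")
  fu <- freq_axis(nrow(ch))
  fv <- freq_axis(ncol(ch))
  G <- exp(-outer(fu^2, fv^2, "+") / sigma^2)
  Re(stats::fft(stats::fft(ch) * G, inverse = TRUE)) / length(ch)
}

#' Magnitude of the image Laplacian
#'
#' Second partial derivatives along rows and columns by central finite
#' differences with replicate-padded borders; returns
#' `sqrt((d2f/dx2)^2 + (d2f/dy2)^2)` per pixel.  Affine intensity fields map
#' to zero; the operator responds strongly to thin lines and weak edges,
#' which is what makes it the texture front-end of the pipeline.
#'
#' @param ch numeric matrix, at least 3 x 3.
#' @return non-negative matrix of the same shape.
#' @export
laplacian_magnitude <- function(ch) {
  stop_if_not(is.matrix(ch) && nrow(ch) >= 3 && ncol(ch) >= 3,
              "image must be at least 3 x 3")
  nr <- nrow(ch)
  nc <- ncol(ch)
  up <- ch[c(1, 1:(nr - 1)), ]
  dn <- ch[c(2:nr, nr), ]
  lf <- ch[, c(1, 1:(nc - 1))]
  rt <- ch[, c(2:nc, nc)]
  d2row <- up + dn - 2 * ch
  d2col <- lf + rt - 2 * ch
  sqrt(d2row^2 + d2col^2)
}

#' Full per-image cleaning chain
#'
#' red channel -> crack detection -> harmonic crack filling ->
#' Fourier Gaussian low-pass -> Laplacian magnitude.  All stages preserve
#' the raster shape and operate in floating point.
#'
#' @param img RGB array.
#' @param alpha crack detection threshold, see [detect_cracks()].
#' @param sigma low-pass width in cycles per pixel, see [gaussian_lowpass()].
#' @return list with `laplacian` (the texture image handed to the polar
#'   stage), `filled` (the cleaned red channel) and `crack_mask`.
#' @export
preprocess_image <- function(img, alpha = 200, sigma = 0.01) {
  ch <- red_channel(img)
  mask <- detect_cracks(img, alpha)
  filled <- fill_cracks(ch, mask)
  smooth <- gaussian_lowpass(filled, sigma)
  list(laplacian = laplacian_magnitude(smooth),
       filled = filled,
       crack_mask = mask)
}
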