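## Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

## Deterministic per-cell seed derivation: every (participant, condition,
## replicate) cell gets its own RNG stream derived from the master seed, so
## a study is reproducible cell-by-cell. Kept below 2^31 - 1.
cell_seed <- function(master_seed, participant, condition_index, replicate = 0L) {
  m <- as.double(master_seed) %% 2147483647
  s <- (m * 48271 +
          as.double(participant) * 2654435 +
          as.double(condition_index) * 97003 +
          as.double(replicate) * 7919) %% 2147483647
  as.integer(s) + 1L
}

## Signed frequency magnitude axis in cycles per pixel for an n-point DFT.
## Only f^2 enters the Gaussian transfer function, so min(k, n-k)/n suffices.
freq_axis <- function(n) {
  k <- 0:(n - 1)
  pmin(k, n - k) / n
}

## Bilinear interpolation of matrix `ch` at fractional (row, col) positions.
## Positions outside the raster are clamped to the border value.
bilinear_sample <- function(ch, row, col) {
  nr <- nrow(ch)
  nc <- ncol(ch)
  r <- pmin(pmax(as.vector(row), 1), nr)
  c <- pmin(pmax(as.vector(col), 1), nc)
  r0 <- pmin(floor(r), nr - 1)
  c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0
  fc <- c - c0
  ch[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    ch[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    ch[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    ch[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Low-pass width matched to droplet scale
#'
#' The Gaussian low-pass width is quoted in cycles per pixel, which is a
#' resolution-dependent unit: the same physical cutoff corresponds to a
#' larger width (in cycles/pixel) on a smaller droplet.  This helper converts
#' a resolution-independent cutoff, expressed in cycles per droplet radius,
#' into cycles per pixel.  The default of 3 cycles per radius reproduces
#' 0.01 cycles/pixel on a 300 px-radius droplet.
#'
#' @param radius_px droplet radius in pixels.
#' @param cycles_per_radius cutoff in cycles per droplet radius.
#' @return Gaussian width in cycles per pixel.
#' @export
scaled_sigma <- function(radius_px, cycles_per_radius = 3) {
  stop_if_not(radius_px > 0, "radius_px must be positive")
  cycles_per_radius / radius_px
}
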