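test_that("centre detection recovers known geometry", {
  # centred dark disc: centroid at the image midpoint, radius from area
  n <- 512
  m <- matrix(0.8, n, n)
  d <- (1:n) - (n + 1) / 2
  m[sqrt(outer(d^2, d^2, "+")) <= 100] <- 0.3
  cen <- find_centre(m)
  expect_lt(max(abs(cen$centre - (n + 1) / 2)), 0.5)
  expect_lt(abs(cen$radius / 100 - 1), 0.01)

  # synthetic droplet with cracks and noise: centre within 2 px, radius 3%
  des <- tiny_design()
  img <- generate_droplet_image(des, droplet_phenotype(angular_mode = 12), 0.3, 42)
  ch <- fill_cracks(red_channel(img), detect_cracks(img))
  cen2 <- find_centre(ch)
  expect_lt(max(abs(cen2$centre - attr(img, "centre"))), 2)
  expect_lt(abs(cen2$radius / attr(img, "radius") - 1), 0.03)

  # blank image: no deposit
  expect_error(find_centre(matrix(5, 64, 64)), "no deposit")
})

test_that("polar resampling is exact on symmetric fields and equivariant to frame rotation", {
  n <- 160
  d <- (1:n) - (n + 1) / 2
  rr <- sqrt(outer(d^2, d^2, "+"))

  # purely radial smooth field: rows constant along theta up to bilinear error
  ring <- exp(-((rr - 40) / 20)^2)
  pol <- to_polar(ring, c((n + 1) / 2, (n + 1) / 2), 60)
  spread <- apply(pol, 1, stats::sd) / pmax(apply(pol, 1, function(x) abs(mean(x))), 1e-6)
  expect_lt(max(spread[apply(pol, 1, mean) > 0.1]), 1e-3)

  # constant image -> constant polar image
  polc <- to_polar(matrix(3, n, n), c(80.5, 80.5), 60)
  expect_lt(max(abs(polc - 3)), 1e-12)

  # theta0 = one grid step reproduces the circular column shift exactly
  th <- atan2(matrix(d, n, n), matrix(d, n, n, byrow = TRUE))
  tex <- (1 + 0.3 * cos(5 * th)) * exp(-((rr - 40) / 10)^2)
  p0 <- to_polar(tex, c(80.5, 80.5), 60)
  p1 <- to_polar(tex, c(80.5, 80.5), 60, theta0 = 2 * pi / 103)
  expect_lt(max(abs(unclass(p1)[, 1:102] - unclass(p0)[, 2:103])), 1e-12)

  # raster rotation by one grid step lands near the shifted grid (lossy)
  texr <- rotate_image(tex, 2 * pi / 103, centre = c(80.5, 80.5))
  p2 <- to_polar(texr, c(80.5, 80.5), 60)
  expect_lt(max(abs(unclass(p2)[, 2:103] - unclass(p0)[, 1:102])), 0.05)

  expect_error(to_polar(ring, c(80.5, 80.5), radius = 30), "exceed n_r")
})

test_that("the angular spectrum finds injected modes and ignores circular shifts", {
  n_theta <- 103
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  pol <- rbind(exp(cos(12 * th)), exp(cos(12 * th)), exp(cos(3 * th)))

  sf <- log_power_spectrum(structure(pol, class = "matrix"))
  g <- sf$gamma
  expect_identical(dim(g), dim(pol))
  # log removes the exponential; the FFT line sits at the injected mode
  expect_equal(which.max(g[1, 2:52]), 12)
  expect_equal(which.max(g[3, 2:52]), 3)

  # circular shift leaves the magnitude spectrum untouched (prime-length
  # DFT rounding is the only residual)
  shifted <- pol[, c(40:n_theta, 1:39)]
  expect_lt(max(abs(log_power_spectrum(shifted)$gamma - g)), 1e-8)

  # constant rows: all non-DC bins sit on the eps floor
  cst <- matrix(5, 2, n_theta)
  gc <- log_power_spectrum(cst)$gamma
  expect_lt(max(gc[, 2:n_theta]), log(1e-4))

  expect_error(log_power_spectrum(matrix(-1, 3, 103)), "non-negative")
})

test_that("feature truncation keeps 47 radial rows x 52 frequency columns, row-major", {
  g <- matrix(0, 48, 103)
  for (i in 1:48) for (j in 1:103) g[i, j] <- 1000 * i + j
  v <- truncate_features(g)
  expect_length(v, 2444)
  expect_equal(attr(v, "n_rows"), 47)
  expect_equal(attr(v, "n_cols"), 52)
  # element (radial row 2, frequency col 1) leads; then frequencies vary fastest
  expect_equal(v[1], 2001)
  expect_equal(v[52], 2052)
  expect_equal(v[53], 3001)
  expect_equal(v[2444], 48052)

  expect_equal(truncate_features(matrix(1, 48, 103)), rep(1, 2444),
               ignore_attr = TRUE)
  expect_error(truncate_features(matrix(1, 1, 10)), ">= 2")
})

test_that("averaging and min-max normalisation behave as specified", {
  v <- c(3, 1, 5, 2)
  n1 <- average_and_normalise(cbind(v), k = 1)
  expect_equal(n1, (v - 1) / 4)
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)

  # identical replicates: k = all equals k = 1
  m <- cbind(v, v, v)
  expect_equal(average_and_normalise(m, "all"), average_and_normalise(m, 1))

  expect_warning(z <- average_and_normalise(cbind(rep(2, 4)), 1), "constant")
  expect_equal(z, rep(0, 4))
  expect_error(average_and_normalise(m, 5), "k must lie")

  # condition matrices: every column spans [0, 1] exactly
  cells <- list(p1 = cbind(rnorm(10)), p2 = cbind(rnorm(10)), p3 = cbind(rnorm(10)))
  cm <- condition_matrix(cells)
  expect_equal(unname(apply(cm, 2, min)), rep(0, 3))
  expect_equal(unname(apply(cm, 2, max)), rep(1, 3))
})

test_that("feature vectors are exactly invariant to polar-frame rotations by grid steps", {
  des <- tiny_design()
  img <- generate_droplet_image(des, droplet_phenotype(angular_mode = 12), 0.3, 42)
  sg <- tiny_sigma()
  v0 <- image_features(img, sigma = sg)
  for (k in c(1, 7, 51)) {
    vk <- image_features(img, sigma = sg, theta0 = 2 * pi * k / 103)
    expect_lt(max(abs(vk - v0)) / diff(range(v0)), 1e-6)
  }
})

test_that("the angular-mode readout is stable under arbitrary rotations of the droplet", {
  # the Laplacian magnitude rectifies the cosine texture, so an injected
  # mode m shows up dominantly at its doubled harmonic 2m; that leading
  # line must not move with orientation
  des <- tiny_design()
  sg <- tiny_sigma()
  top_col <- function(rot) {
    img <- generate_droplet_image(des, smooth_phenotype(angular_mode = 9),
                                  rotation = rot, seed = 5)
    v <- image_features(img, sigma = sg)
    g <- matrix(v, 47, 52, byrow = TRUE)
    cs <- colSums(g[25:47, ])          # corona rows carry the texture
    which.max(cs[-1])                  # frequency in cycles/rev (non-DC)
  }
  for (rot in c(0, 0.26, 1.1, 2.5)) expect_equal(top_col(rot), 2 * 9)
})
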