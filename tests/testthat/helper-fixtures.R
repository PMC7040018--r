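# Shared fixtures, all generated in code.

# small imaging design used across files (radius must exceed n_r = 48)
tiny_design <- function(n_participants = 4, conditions = c("baseline", "rec6"),
                        images_per_cell = 3, master_seed = 7) {
  study_design(n_participants = n_participants, conditions = conditions,
               images_per_cell = images_per_cell, image_size_px = 160,
               droplet_radius_px = 64, master_seed = master_seed)
}

tiny_sigma <- function() scaled_sigma(64)

# a droplet whose angular content is entirely smooth (no cracks, no noise):
# the cleanest probe of the spectral stages
smooth_phenotype <- function(angular_mode = 12) {
  droplet_phenotype(angular_mode = angular_mode, n_radial_cracks = 0,
                    central_crack_density = 0, noise_sd = 0)
}

# two-class Gaussian feature matrices (features x participants) for the
# discriminator and optimiser tests: class means +- sep/2 along feature 1
gaussian_cohorts <- function(n_per_class = 4, n_feat = 5, sep = 2, sd = 1,
                             seed = 1) {
  withr::with_seed(seed, {
    mA <- matrix(rnorm(n_feat * n_per_class, 0, sd), n_feat)
    mB <- matrix(rnorm(n_feat * n_per_class, 0, sd), n_feat)
    mA[1, ] <- mA[1, ] - sep / 2
    mB[1, ] <- mB[1, ] + sep / 2
    list(A = mA, B = mB)
  })
}

# mean silhouette width between two labelled point sets (Euclidean)
two_group_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  ulab <- unique(labels)
  stopifnot(length(ulab) == 2)
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# dense brute-force solution of the generalised eigenproblem Sb v = l Sw v
# (the independent oracle for fit_lda's leading direction)
brute_force_lda_direction <- function(scores, labels, lambda_rel = 1e-6) {
  classes <- unique(labels)
  p <- ncol(scores)
  mu_all <- colMeans(scores)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in classes) {
    Sc <- scores[labels == cl, , drop = FALSE]
    mu_c <- colMeans(Sc)
    Sw <- Sw + crossprod(sweep(Sc, 2, mu_c))
    Sb <- Sb + nrow(Sc) * tcrossprod(mu_c - mu_all)
  }
  Swr <- Sw + diag(lambda_rel * sum(diag(Sw)) / p, p)
  ev <- eigen(solve(Swr, Sb))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v / sqrt(sum(v^2))
}

abs_cos <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
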