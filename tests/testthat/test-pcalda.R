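test_that("PCA recovers the variance structure and the retained-score rule", {
  # collinear points: one component carries all variance
  t <- seq(-2, 2, length.out = 9)
  X <- cbind(t, 2 * t, -t) + 5
  p <- fit_pca(X)
  expect_gt(p$sdev[1]^2 / sum(p$sdev^2), 1 - 1e-12)

  # completeness: all components reconstruct the data
  set.seed(3)
  X2 <- matrix(rnorm(6 * 10), 6, 10)
  p2 <- fit_pca(X2)
  rec <- predict(p2, X2, n_keep = ncol(p2$loadings)) %*%
    t(p2$loadings) + matrix(p2$mean, 6, 10, byrow = TRUE)
  expect_lt(max(abs(rec - X2)), 1e-8)

  # half-the-scores rule: 6 samples -> floor(5/2) = 2 retained
  expect_equal(p2$n_keep, 2L)

  # orthonormal loadings
  G <- crossprod(p2$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)

  expect_error(fit_pca(matrix(1, 4, 3)), "identical")
})

test_that("PCA scores are invariant (up to sign) under a common orthogonal rotation", {
  set.seed(8)
  X <- matrix(rnorm(8 * 6), 8, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  s1 <- predict(fit_pca(X), X)
  s2 <- predict(fit_pca(X %*% Q), X %*% Q)
  for (j in seq_len(ncol(s1))) {
    expect_lt(min(max(abs(s1[, j] - s2[, j])), max(abs(s1[, j] + s2[, j]))), 1e-6)
  }
})

test_that("the leading discriminant matches closed forms and a brute-force solve", {
  # well-separated clouds displaced along a known direction
  set.seed(11)
  u <- c(1, 0, 0, 0)
  S <- rbind(matrix(rnorm(240, 0, 0.2), 60, 4),
             matrix(rnorm(240, 0, 0.2), 60, 4) + matrix(5 * u, 60, 4, byrow = TRUE))
  lab <- rep(c("A", "B"), each = 60)
  m <- fit_lda(S, lab)
  expect_gt(abs_cos(m$directions[, 1], u), 0.99)
  expect_equal(sqrt(colSums(m$directions^2)), c(LD_S1 = 1, LD_S2 = 1))

  # isotropic within-class scatter in 2D: LD_S1 is the mean-difference line
  set.seed(12)
  ang <- runif(200, 0, 2 * pi); rad <- sqrt(runif(200))
  iso <- cbind(rad * cos(ang), rad * sin(ang))
  mu_shift <- c(2, 3) / sqrt(13)
  S2 <- rbind(iso[1:100, ], sweep(iso[101:200, ], 2, -4 * mu_shift))
  m2 <- fit_lda(S2, rep(c("A", "B"), each = 100))
  expect_gt(abs_cos(m2$directions[, 1], mu_shift), 0.98)

  # equal class means: centroids coincide along LD_S1
  set.seed(13)
  S3 <- matrix(rnorm(40), 20, 2)
  S3 <- sweep(S3, 2, colMeans(S3))
  m3 <- fit_lda(rbind(S3, S3), rep(c("A", "B"), each = 20))
  expect_lt(abs(diff(m3$centroids[, 1])), 1e-8)

  # oracle equivalence on small random instances
  for (s in 1:10) {
    set.seed(300 + s)
    n <- sample(6:8, 1); p <- sample(2:4, 1)
    Ss <- matrix(rnorm(n * p), n, p)
    Ss[1:(n %/% 2), 1] <- Ss[1:(n %/% 2), 1] + 2
    labs <- rep(c("A", "B"), c(n %/% 2, n - n %/% 2))
    got <- fit_lda(Ss, labs)$directions[, 1]
    want <- brute_force_lda_direction(Ss, labs)
    expect_gt(abs_cos(got, want), 1 - 1e-6)
  }

  expect_error(fit_lda(S, rep("A", 20)), "two classes")
  expect_error(fit_lda(S[1:11, ], rep(c("A", "B"), c(10, 1))), ">= 2 samples")
})

test_that("the distance-ratio rule equals nearest-centroid assignment", {
  set.seed(21)
  S <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 3, 1), 30, 2))
  lab <- rep(c("A", "B"), each = 30)
  m <- fit_lda(S, lab)

  # a sample placed exactly at a centroid (directions are square here)
  at_A <- m$centroids[1, , drop = FALSE] %*% solve(m$directions)
  rep_A <- classify(m, at_A)
  expect_equal(rep_A$samples$predicted, "A")
  expect_lt(rep_A$samples$ratio, 1e-8)

  # equidistant: tie convention assigns the first class and flags it
  mid <- matrix(colMeans(m$centroids), 1) %*% solve(m$directions)
  rep_mid <- classify(m, mid)
  expect_equal(rep_mid$samples$predicted, "A")
  expect_true(rep_mid$samples$tie)

  # ratio < 1 iff nearer centroid, on 1000 random draws
  X <- matrix(rnorm(2000, 1.5, 2), 1000, 2)
  P <- X %*% m$directions
  near <- ifelse(sqrt(rowSums(sweep(P, 2, m$centroids[1, ])^2)) <=
                 sqrt(rowSums(sweep(P, 2, m$centroids[2, ])^2)), "A", "B")
  expect_identical(classify(m, X)$samples$predicted, near)

  # error rate is invariant under class relabelling
  r1 <- classify(m, S, lab)
  m_sw <- fit_lda(S, ifelse(lab == "A", "B", "A"))
  r2 <- classify(m_sw, S, ifelse(lab == "A", "B", "A"))
  expect_equal(r1$error_rate, r2$error_rate)
  expect_equal(r1$error_rate, 100 * length(r1$misclassified) / length(lab))
})

test_that("discriminant maps back-project linearly and keep orthogonality", {
  set.seed(31)
  X <- matrix(rnorm(12 * 2444), 12)
  X[7:12, 5] <- X[7:12, 5] + 6
  pca <- fit_pca(X)
  lda <- fit_lda(predict(pca, X), rep(c("A", "B"), each = 6))
  maps <- ld_function_map(pca, lda)
  expect_identical(dim(maps$ld1), c(47L, 52L))

  # an axis-aligned "discriminant" returns the loading itself
  fake <- lda
  fake$directions <- diag(pca$n_keep)[, 1:2]
  m1 <- ld_function_map(pca, fake)
  expect_equal(as.vector(t(m1$ld1)), pca$loadings[, 1], tolerance = 1e-12)

  # projecting the maps back into PC space preserves LD orthogonality in
  # the retained basis (loadings are orthonormal)
  b1 <- crossprod(pca$loadings[, 1:pca$n_keep], as.vector(t(maps$ld1)))
  b2 <- crossprod(pca$loadings[, 1:pca$n_keep], as.vector(t(maps$ld2)))
  expect_equal(sum(b1 * b2), sum(lda$directions[, 1] * lda$directions[, 2]),
               tolerance = 1e-8)
})

test_that("condition centroids order monotonically along LD_S1 under a graded shift", {
  set.seed(41)
  base <- matrix(rnorm(2444 * 6, 0, 0.1), 2444)
  dir <- rnorm(2444); dir <- dir / sqrt(sum(dir^2))
  mats <- lapply(c(0, 1, 2), function(s) base + s * dir)
  names(mats) <- c("c0", "c1", "c2")
  X <- t(cbind(mats$c0, mats$c2))
  pca <- fit_pca(X)
  lda <- fit_lda(predict(pca, X), rep(c("c0", "c2"), each = 6))
  traj <- centroid_trajectory(pca, lda, mats)
  expect_equal(traj$condition, c("c0", "c1", "c2"))
  expect_equal(cor(traj$ld_s1, 1:3, method = "spearman"), 1)

  # identical clouds: centroids coincide
  traj2 <- centroid_trajectory(pca, lda, list(a = mats$c0, b = mats$c0))
  expect_lt(abs(diff(traj2$ld_s1)), 1e-10)

  # a single condition yields a single centroid row
  expect_equal(nrow(centroid_trajectory(pca, lda, mats["c0"])), 1)
})
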