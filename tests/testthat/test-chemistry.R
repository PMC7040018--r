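test_that("strong ion difference follows its definition and is linear", {
  # resting cohort means
  expect_equal(strong_ion_difference(141, 4.0, 1.23, 105, 1.1), 40.13)
  expect_equal(round(strong_ion_difference(141, 4.0, 1.23, 105, 1.1)), 40)
  expect_equal(strong_ion_difference(0, 0, 0, 0, 0), 0)
  expect_equal(strong_ion_difference(140, 4, 1, 100, 5), 40)
  # linearity: doubling all inputs doubles the output
  expect_equal(strong_ion_difference(282, 8, 2.46, 210, 2.2), 2 * 40.13)
  expect_error(strong_ion_difference(140, NA, 1, 100, 5), "missing analyte")
})

test_that("hydrogen ion concentration inverts pH exactly", {
  expect_equal(hydrogen_ion(7.0), 100)
  expect_equal(hydrogen_ion(7.4), 39.81, tolerance = 1e-4)
  expect_equal(hydrogen_ion(6.0), 1000)
  # round trip pH -> [H+] -> pH
  pHs <- c(6.8, 7.1, 7.365, 7.6)
  expect_equal(9 - log10(hydrogen_ion(pHs)), pHs, tolerance = 1e-9)
  expect_error(hydrogen_ion(NA), "finite")
})

test_that("blood volume change from haemoglobin behaves at the anchors", {
  expect_equal(delta_blood_volume(15, 15), 0)
  expect_equal(delta_blood_volume(15.4, 16.7), -7.78, tolerance = 0.01)
  expect_equal(delta_blood_volume(15, 7.5), 100)
  expect_error(delta_blood_volume(15, 0), "positive")
})

test_that("condition correlation matrices are valid correlation matrices", {
  des <- study_design(n_participants = 30, master_seed = 5)
  panel <- generate_chemistry_table(des, seed = 5)
  # baseline dBV is identically zero (it is defined relative to baseline),
  # so the baseline matrix carries an NA row and a warning
  expect_warning(mats <- condition_correlation_matrices(panel), "zero-variance")
  expect_named(mats, des$conditions)
  expect_true(all(is.na(mats$baseline["dBV", -which(colnames(mats$baseline) == "dBV")])))
  for (M in mats[-1]) {
    expect_identical(dim(M), c(14L, 14L))
    expect_equal(unname(diag(M)), rep(1, 14))
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }

  # estimator anchors: duplicated and negated columns
  toy <- data.frame(participant = 1:20, condition = "x",
                    u = rnorm(20))
  toy$v <- toy$u
  toy$w <- -toy$u
  m <- condition_correlation_matrices(toy, vars = c("u", "v", "w"))$x
  expect_equal(m["u", "v"], 1)
  expect_equal(m["u", "w"], -1)

  # a built-in correlation is recovered within sampling error
  withr::with_seed(99, {
    z <- rnorm(30)
    cor_target <- -0.8
    toy2 <- data.frame(participant = 1:30, condition = "x",
                       pHv = z,
                       pco2 = cor_target * z + sqrt(1 - cor_target^2) * rnorm(30))
  })
  m2 <- condition_correlation_matrices(toy2, vars = c("pHv", "pco2"))$x
  expect_equal(m2["pHv", "pco2"], -0.8, tolerance = 0.15)

  # zero-variance column: NA with a warning, not an error
  toy$z <- 1
  expect_warning(mz <- condition_correlation_matrices(toy, vars = c("u", "z"))$x,
                 "zero-variance")
  expect_true(is.na(mz["u", "z"]))
})

test_that("chemistry PCA separates baseline from peak and tracks recovery", {
  des <- study_design(n_participants = 30, master_seed = 21)
  panel <- generate_chemistry_table(des, seed = 21)
  res <- chemistry_pca_centroids(panel)
  expect_equal(res$centroids$condition, des$conditions)

  # baseline and peak fall into separated clusters in the PC1-PC2 plane
  sub <- res$scores[res$scores$condition %in% c("baseline", "peak"), ]
  sil <- two_group_silhouette(as.matrix(sub[, c("PC1", "PC2")]), sub$condition)
  expect_gt(sil, 0)

  # identical condition distributions: centroids nearly coincide
  des2 <- study_design(n_participants = 200, conditions = c("baseline", "peak"),
                       master_seed = 2)
  ref <- chemistry_reference()
  ref$mean[ref$condition == "peak"] <- ref$mean[ref$condition == "baseline"]
  ref$sd[ref$condition == "peak"] <- ref$sd[ref$condition == "baseline"]
  panel2 <- generate_chemistry_table(des2, seed = 2, reference = ref)
  res2 <- chemistry_pca_centroids(panel2)
  cent <- as.matrix(res2$centroids[, -1])
  expect_lt(sqrt(sum((cent[1, ] - cent[2, ])^2)), 0.6)

  # degenerate input: single participant, single condition
  des3 <- study_design(n_participants = 2, conditions = "baseline", master_seed = 1)
  panel3 <- generate_chemistry_table(des3, sd_scale = 0)
  expect_error(chemistry_pca_centroids(panel3), "zero-variance")
})
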