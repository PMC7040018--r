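#' Extract per-image feature vectors for a study
#'
#' Renders every image of the requested conditions and runs the full
#' image-to-feature chain ([image_features()]).  The result is the raw
#' replicate-level feature store from which condition matrices at any
#' averaging depth `k` can be assembled without re-touching pixels.
#'
#' @param study a `dd_study`.
#' @param conditions conditions to process (default: all in the design).
#' @param alpha crack threshold; `sigma` low-pass width in cycles/pixel
#'   (default: [scaled_sigma()] of the design's droplet radius).
#' @param sigma,n_r,n_theta,eps see [image_features()].
#' @param progress print a line per condition.
#' @return nested list `res[[condition]][[participant]]`: features x
#'   replicates matrix, replicates in manifest order.
#' @export
study_feature_vectors <- function(study, conditions = study$design$conditions,
                                  alpha = 200,
                                  sigma = scaled_sigma(study$design$droplet_radius_px),
                                  n_r = 48, n_theta = 103, eps = 1e-6,
                                  progress = FALSE) {
  stopifnot(inherits(study, "dd_study"))
  m <- study$manifest
  out <- list()
  for (cd in conditions) {
    if (progress) message("features: condition ", cd)
    rows_cd <- which(m$condition == cd)
    parts <- sort(unique(m$participant[rows_cd]))
    out[[cd]] <- lapply(parts, function(p) {
      rr <- rows_cd[m$participant[rows_cd] == p]
      rr <- rr[order(m$replicate[rr])]
      vapply(rr, function(i) {
        as.numeric(image_features(study_image(study, i), alpha = alpha,
                                  sigma = sigma, n_r = n_r, n_theta = n_theta,
                                  eps = eps))
      }, numeric((n_r - 1) * ceiling(n_theta / 2)))
    })
    names(out[[cd]]) <- paste0("p", parts)
  }
  out
}

#' Optimised two-condition discrimination
#'
#' The headline experiment: render (or reuse) the study's features for one
#' condition pair, average `k` replicates per participant and min-max
#' normalise, run the two-stage greedy training-subset optimisation, and
#' refit the final PCA + LDA on the chosen training split.  Deterministic
#' given the study (whose manifest fixes every seed).
#'
#' @param study a `dd_study`.
#' @param pair length-2 character vector of distinct conditions
#'   (default: first and last condition of the design).
#' @param k replicates averaged per participant (`"all"` or a count).
#' @param features optional precomputed [study_feature_vectors()] result.
#' @param cfg an [optimiser_config()].
#' @param n_r,n_theta polar grid of the feature extraction.
#' @param ... further pre-processing arguments passed to
#'   [study_feature_vectors()] (`alpha`, `sigma`, `eps`).
#' @return list of class `dd_run`: `error_rate` (%), `optimiser`
#'   (`dd_opt`), `pca`, `lda`, `report` (all-sample classification),
#'   `maps` (LD-function maps), `matrices` (the two condition matrices).
#' @export
run_discrimination <- function(study, pair = NULL, k = "all",
                               features = NULL, cfg = optimiser_config(),
                               n_r = 48, n_theta = 103, ...) {
  stopifnot(inherits(study, "dd_study"))
  pair <- pair %||% study$design$conditions[c(1, length(study$design$conditions))]
  stop_if_not(length(pair) == 2 && pair[1] != pair[2],
              "pair must name two distinct conditions")
  stop_if_not(all(pair %in% study$design$conditions),
              "unknown condition(s): %s",
              paste(setdiff(pair, study$design$conditions), collapse = ", "))
  if (is.null(features)) {
    features <- study_feature_vectors(study, conditions = pair,
                                      n_r = n_r, n_theta = n_theta, ...)
  }
  mA <- condition_matrix(features[[pair[1]]], k = k)
  mB <- condition_matrix(features[[pair[2]]], k = k)
  stop_if_not(nrow(mA) == (n_r - 1) * ceiling(n_theta / 2),
              "feature length does not match the stated polar grid")

  opt <- optimise_training(mA, mB, cfg = cfg)

  Xtr <- t(cbind(mA[, opt$subset_A, drop = FALSE], mB[, opt$subset_B, drop = FALSE]))
  lab_tr <- rep(pair, c(length(opt$subset_A), length(opt$subset_B)))
  pca <- fit_pca(Xtr)
  pca$n_keep <- min(max(2L, pca$n_keep), ncol(pca$loadings))
  lda <- fit_lda(predict(pca, Xtr), lab_tr)
  Xall <- t(cbind(mA, mB))
  truth <- rep(pair, c(ncol(mA), ncol(mB)))
  report <- classify(lda, predict(pca, Xall), truth)
  maps <- ld_function_map(pca, lda, n_rows = n_r - 1,
                          n_cols = ceiling(n_theta / 2))

  structure(list(error_rate = report$error_rate, optimiser = opt,
                 pca = pca, lda = lda, report = report, maps = maps,
                 matrices = stats::setNames(list(mA, mB), pair), k = k),
            class = "dd_run")
}

#' Averaging sweep
#'
#' Re-runs the full optimised discrimination for each averaging depth `k`
#' (the optimiser is re-run per case) on a shared replicate-level feature
#' store, and tabulates error against `k` — the replicate-averaging curve.
#'
#' @param study a `dd_study`.
#' @param pair condition pair, as in [run_discrimination()].
#' @param k_values averaging depths; `"all"` is allowed as an entry.
#' @param features optional precomputed feature store.
#' @param cfg an [optimiser_config()].
#' @param ... pre-processing arguments for [study_feature_vectors()].
#' @param n_r,n_theta polar grid of the feature extraction.
#' @return data frame: `k` (character), `error` (%); attribute `runs` holds
#'   the individual `dd_run` objects.
#' @export
averaging_sweep <- function(study, pair = NULL, k_values = list(1, "all"),
                            features = NULL, cfg = optimiser_config(),
                            n_r = 48, n_theta = 103, ...) {
  stopifnot(inherits(study, "dd_study"))
  pair <- pair %||% study$design$conditions[c(1, length(study$design$conditions))]
  if (is.null(features)) {
    features <- study_feature_vectors(study, conditions = pair,
                                      n_r = n_r, n_theta = n_theta, ...)
  }
  n_rep_min <- min(vapply(unlist(features, recursive = FALSE), ncol, integer(1)))
  runs <- lapply(k_values, function(k) {
    if (!identical(k, "all")) {
      stop_if_not(k >= 1 && k <= n_rep_min,
                  "k = %s exceeds the available replicates (%d)", format(k), n_rep_min)
    }
    run_discrimination(study, pair = pair, k = k, features = features,
                       cfg = cfg, n_r = n_r, n_theta = n_theta)
  })
  out <- data.frame(k = vapply(k_values, function(k) as.character(k), character(1)),
                    error = vapply(runs, function(r) r$error_rate, numeric(1)),
                    stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  out
}
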