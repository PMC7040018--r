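#' Fit a PCA basis to feature vectors
#'
#' Column-centres the sample matrix and takes the singular value
#' decomposition; loadings are the right singular vectors (orthonormal,
#' ordered by decreasing explained variance).  At most `n_samples - 1`
#' non-trivial components exist.  The default number of retained scores for
#' the downstream discriminant is half the non-trivial components,
#' `n_keep = floor(n_nonzero / 2)`.
#'
#' @param X samples x features matrix (>= 2 samples).
#' @param n_keep retained scores; `NULL` for the default rule.
#' @return object of class `dd_pca`: `mean`, `loadings` (features x
#'   n_components), `sdev`, `n_keep`.
#' @export
fit_pca <- function(X, n_keep = NULL) {
  X <- as.matrix(X)
  stop_if_not(nrow(X) >= 2, "need at least 2 samples, got %d", nrow(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  stop_if_not(sv$d[1] > 1e-12, "all samples identical: PCA undefined")
  n_nonzero <- sum(sv$d > 1e-10 * sv$d[1])
  n_nonzero <- min(n_nonzero, nrow(X) - 1L)
  if (is.null(n_keep)) n_keep <- max(1L, n_nonzero %/% 2L)
  stop_if_not(n_keep >= 1 && n_keep <= n_nonzero,
              "n_keep must lie in 1..%d", n_nonzero)
  structure(list(mean = mu,
                 loadings = sv$v[, seq_len(n_nonzero), drop = FALSE],
                 sdev = sv$d[seq_len(n_nonzero)] / sqrt(max(1, nrow(X) - 1)),
                 n_keep = as.integer(n_keep)),
            class = "dd_pca")
}

#' Project feature vectors onto retained PCA scores
#'
#' @param object a `dd_pca` model.
#' @param newdata samples x features matrix (or a single vector).
#' @param n_keep override the model's retained-score count.
#' @param ... unused.
#' @return samples x n_keep score matrix.
#' @export
predict.dd_pca <- function(object, newdata, n_keep = object$n_keep, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  sweep(X, 2, object$mean) %*% object$loadings[, seq_len(n_keep), drop = FALSE]
}

#' Fit a two-axis linear discriminant in PCA-score space
#'
#' Solves the generalised eigenproblem of between-class versus within-class
#' scatter, with the within-class scatter ridge-regularised by
#' `lambda = 1e-6 * trace(Sw) / n_keep` (retained scores can approach the
#' sample count).  For two classes the between-class scatter has rank one,
#' so only one canonical discriminant exists; the second axis is taken as
#' the eigenvector with the second-largest eigenvalue of the same
#' regularised problem — the leading direction of residual structure in the
#' within-class metric — giving the two-dimensional discriminant space the
#' decision rule operates in.  Both directions are unit-norm with a
#' deterministic sign (largest-magnitude coordinate positive).
#'
#' @param scores samples x n_keep PCA score matrix (n_keep >= 2).
#' @param labels two-class factor/character vector (each class >= 2 samples).
#' @param lambda_rel relative ridge on the within-class scatter.
#' @return object of class `dd_lda`: `directions` (n_keep x 2, columns
#'   LD_S1/LD_S2), `centroids` (2 x 2, one row per class), `classes`,
#'   `projections` (training samples in discriminant space), `lambda`.
#' @export
fit_lda <- function(scores, labels, lambda_rel = 1e-6) {
  S <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- unique(labels)
  stop_if_not(length(classes) == 2, "exactly two classes required, got %d",
              length(classes))
  n_c <- table(factor(labels, levels = classes))
  stop_if_not(all(n_c >= 2), "each class needs >= 2 samples (got %s)",
              paste(n_c, collapse = ", "))
  p <- ncol(S)
  stop_if_not(p >= 2, "need at least 2 retained scores, got %d", p)

  mu_all <- colMeans(S)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in classes) {
    Sc <- S[labels == cl, , drop = FALSE]
    mu_c <- colMeans(Sc)
    Sw <- Sw + crossprod(sweep(Sc, 2, mu_c))
    Sb <- Sb + nrow(Sc) * tcrossprod(mu_c - mu_all)
  }
  ## ridge scale: within-class trace, falling back to the between-class
  ## trace when every class is internally identical (the discriminant then
  ## reduces to the Euclidean mean-difference direction)
  tr <- sum(diag(Sw))
  if (tr <= 0) tr <- sum(diag(Sb))
  stop_if_not(tr > 0, "scatter matrices are singular: all samples identical")
  lambda <- lambda_rel * tr / p
  Swr <- Sw + diag(lambda, p)

  ## whiten in the Sw metric, then an ordinary symmetric eigenproblem
  ew <- eigen(Swr, symmetric = TRUE)
  W <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  M <- W %*% Sb %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  dirs <- W %*% em$vectors[, 1:2, drop = FALSE]
  dirs <- apply(dirs, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  colnames(dirs) <- c("LD_S1", "LD_S2")

  proj <- S %*% dirs
  cent <- rbind(colMeans(proj[labels == classes[1], , drop = FALSE]),
                colMeans(proj[labels == classes[2], , drop = FALSE]))
  rownames(cent) <- classes
  structure(list(directions = dirs, centroids = cent, classes = classes,
                 projections = proj, labels = labels, lambda = lambda,
                 eigenvalues = em$values[1:2]),
            class = "dd_lda")
}

#' Classify samples by the centroid distance-ratio rule
#'
#' Projects each sample into the (LD_S1, LD_S2) plane and computes its
#' Euclidean distances `d_A`, `d_B` to the two training centroids.  A
#' sample is assigned to the first class iff `d_A / d_B < 1`; exact ties
#' (`ratio == 1`) go to the first class by fixed convention and are flagged.
#'
#' @param model a fitted `dd_lda`.
#' @param scores samples x n_keep PCA scores to classify.
#' @param truth optional ground-truth labels; enables the error rate.
#' @return object of class `dd_report`: data frame `samples` (predicted,
#'   ratio, tie, ld_s1, ld_s2, truth), `error_rate` (percent, `NA` without
#'   truth) and `misclassified` indices.
#' @export
classify <- function(model, scores, truth = NULL) {
  stop_if_not(inherits(model, "dd_lda"), "model must be a fitted dd_lda")
  S <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else as.matrix(scores)
  P <- S %*% model$directions
  dA <- sqrt(rowSums(sweep(P, 2, model$centroids[1, ])^2))
  dB <- sqrt(rowSums(sweep(P, 2, model$centroids[2, ])^2))
  ratio <- ifelse(dB == 0, ifelse(dA == 0, 1, Inf), dA / dB)
  # numerically equidistant samples go to the first class by convention
  tie <- abs(dA - dB) <= 1e-12 * (dA + dB)
  pred <- ifelse(ratio <= 1 | tie, model$classes[1], model$classes[2])
  samples <- data.frame(predicted = pred, ratio = ratio, tie = tie,
                        ld_s1 = P[, 1], ld_s2 = P[, 2],
                        stringsAsFactors = FALSE)
  err <- NA_real_
  mis <- integer(0)
  if (!is.null(truth)) {
    truth <- as.character(truth)
    samples$truth <- truth
    mis <- which(pred != truth)
    err <- 100 * length(mis) / length(pred)
  }
  structure(list(samples = samples, error_rate = err, misclassified = mis),
            class = "dd_report")
}

#' Back-project the discriminant axes into feature space
#'
#' Maps each LD direction through the retained PCA loadings back into the
#' original feature space and reshapes it to the (radius x frequency) block
#' the features were flattened from — the discriminant-function maps whose
#' signed patches show, per radius and angular frequency (cycles per
#' revolution), where the discriminating texture lives.
#'
#' @param pca the `dd_pca` used for the discriminant.
#' @param model the fitted `dd_lda`.
#' @param n_rows,n_cols shape of the spectral block (47 x 52 at defaults).
#' @return list of two `n_rows x n_cols` signed matrices, `ld1` and `ld2`.
#' @export
ld_function_map <- function(pca, model, n_rows = 47, n_cols = 52) {
  L <- pca$loadings[, seq_len(nrow(model$directions)), drop = FALSE]
  stop_if_not(nrow(L) == n_rows * n_cols,
              "feature length %d does not match %d x %d", nrow(L), n_rows, n_cols)
  back <- L %*% model$directions
  list(ld1 = matrix(back[, 1], n_rows, n_cols, byrow = TRUE),
       ld2 = matrix(back[, 2], n_rows, n_cols, byrow = TRUE))
}

#' Condition centroids in a common discriminant projection
#'
#' Projects each condition's feature matrix through one fitted PCA + LDA
#' pair and returns the per-condition centroid coordinates in
#' (LD_S1, LD_S2), in the order given — the droplet-side condition
#' trajectory.
#'
#' @param pca fitted `dd_pca`.
#' @param model fitted `dd_lda`.
#' @param condition_matrices named list of feature matrices
#'   (features x participants), in condition order.
#' @return data frame: condition, ld_s1, ld_s2, n.
#' @export
centroid_trajectory <- function(pca, model, condition_matrices) {
  stop_if_not(length(condition_matrices) >= 1, "no conditions supplied")
  rows <- lapply(names(condition_matrices), function(cd) {
    m <- condition_matrices[[cd]]
    stop_if_not(ncol(m) >= 1, "condition '%s' is empty", cd)
    P <- predict(pca, t(m)) %*% model$directions
    data.frame(condition = cd, ld_s1 = mean(P[, 1]), ld_s2 = mean(P[, 2]),
               n = ncol(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
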