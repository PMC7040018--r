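#' Strong ion difference
#'
#' `[SID] = ([Na+] + [K+] + [Ca2+]) - ([Cl-] + [La-])`, the difference
#' between the strong cations and strong anions, a principal determinant of
#' blood acid-base status.  All inputs and the result are in mmol/L.
#'
#' @param Na,K,Ca,Cl,La analyte concentrations in mmol/L (vectorised).
#' @return strong ion difference in mmol/L.
#' @export
strong_ion_difference <- function(Na, K, Ca, Cl, La) {
  args <- list(Na = Na, K = K, Ca = Ca, Cl = Cl, La = La)
  for (nm in names(args)) {
    stop_if_not(length(args[[nm]]) > 0 && !anyNA(args[[nm]]),
                "missing analyte: %s", nm)
  }
  (Na + K + Ca) - (Cl + La)
}

#' Hydrogen ion concentration from pH
#'
#' `[H+] = 10^(9 - pH)` nmol/L.
#'
#' @param pH measured pH (vectorised).
#' @return hydrogen ion concentration in nmol/L.
#' @export
hydrogen_ion <- function(pH) {
  stop_if_not(all(is.finite(pH)), "pH must be finite")
  10^(9 - pH)
}

#' Blood volume change from haemoglobin concentration
#'
#' Percentage change in blood volume relative to rest inferred from the
#' haemoglobin concentration ratio: `100 * (Hb_rest / Hb_t - 1)`.
#' Negative values indicate haemoconcentration (volume loss).  This is the
#' Hb-ratio form; haematocrit-corrected variants exist but require a
#' variable the panel does not carry.
#'
#' @param Hb_rest resting haemoglobin, g/dL.
#' @param Hb_t haemoglobin at the time point of interest, g/dL.
#' @return blood volume change in percent.
#' @export
delta_blood_volume <- function(Hb_rest, Hb_t) {
  stop_if_not(all(Hb_rest > 0) && all(Hb_t > 0),
              "haemoglobin concentrations must be positive")
  100 * (Hb_rest / Hb_t - 1)
}

#' Per-condition correlation matrices of the chemistry panel
#'
#' Pearson correlations of the 14 panel variables across participants,
#' one matrix per condition.  Zero-variance columns yield `NA` correlations
#' (with a warning) rather than an error.
#'
#' @param panel a `dd_chemistry` panel.
#' @param vars variables to correlate; defaults to the full 14-variable panel.
#' @return named list of correlation matrices, one per condition, in the
#'   panel's condition order.
#' @export
condition_correlation_matrices <- function(panel, vars = chem_panel_vars()) {
  stopifnot(inherits(panel, "dd_chemistry") || is.data.frame(panel))
  stop_if_not(all(vars %in% names(panel)),
              "panel is missing variables: %s",
              paste(setdiff(vars, names(panel)), collapse = ", "))
  conds <- unique(panel$condition)
  out <- lapply(conds, function(cd) {
    sub <- panel[panel$condition == cd, vars, drop = FALSE]
    stop_if_not(nrow(sub) >= 3, "need >= 3 participants per condition, '%s' has %d",
                cd, nrow(sub))
    zv <- vapply(sub, function(x) stats::sd(x) == 0, logical(1))
    if (any(zv)) {
      warning("zero-variance variable(s): ", paste(vars[zv], collapse = ", "),
              "; correlations reported as NA")
      suppressWarnings(stats::cor(as.matrix(sub)))
    } else {
      stats::cor(as.matrix(sub))
    }
  })
  names(out) <- conds
  out
}

#' Chemistry PCA scores and condition centroids
#'
#' Standardises the 12 independent panel variables (pH and SID are excluded
#' as deterministic functions of the others), runs PCA over all rows pooled,
#' and returns the first three scores per row together with the
#' per-condition centroids in score space, ordered by the panel's condition
#' sequence — the chemistry-side condition trajectory.
#'
#' @param panel a `dd_chemistry` panel.
#' @param n_scores number of leading scores to return.
#' @return list with `scores` (data frame: participant, condition, PC1..),
#'   `centroids` (one row per condition, in order), `sdev` (all PCA standard
#'   deviations) and `loadings`.
#' @export
chemistry_pca_centroids <- function(panel, n_scores = 3) {
  vars <- setdiff(chem_panel_vars(), c("pH", "SID"))
  stop_if_not(all(vars %in% names(panel)),
              "panel is missing variables: %s",
              paste(setdiff(vars, names(panel)), collapse = ", "))
  X <- as.matrix(panel[, vars])
  sds <- apply(X, 2, stats::sd)
  stop_if_not(all(sds > 0),
              "zero-variance variable(s): %s", paste(vars[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_scores, ncol(pc$x))
  scores <- data.frame(participant = panel$participant,
                       condition = panel$condition,
                       pc$x[, seq_len(k), drop = FALSE])
  conds <- unique(panel$condition)
  cent <- t(vapply(conds, function(cd) {
    colMeans(pc$x[panel$condition == cd, seq_len(k), drop = FALSE])
  }, numeric(k)))
  list(scores = scores,
       centroids = data.frame(condition = conds, cent, row.names = NULL),
       sdev = pc$sdev, loadings = pc$rotation)
}
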